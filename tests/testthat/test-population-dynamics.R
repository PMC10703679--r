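toy_cells <- function() {
  data.frame(
    subcluster = c("s1", "s1", "s2", "s1", "s2", "s2"),
    well = c("w1", "w1", "w1", "w2", "w2", "w2"),
    animal = c("a1", "a1", "a1", "a2", "a2", "a2"),
    condition = c("case", "case", "case", "control", "control", "control"),
    sex = c("M", "M", "M", "F", "F", "F")
  )
}

test_that("abundance tables match hand counts and are order invariant", {
  tab <- build_abundance_table(toy_cells())
  expect_equal(tab$counts["s1", "w1"], 2L)
  expect_equal(tab$counts["s2", "w2"], 2L)
  expect_equal(unname(tab$totals), c(3L, 3L))

  set.seed(2)
  perm <- sample(6)
  tab2 <- build_abundance_table(toy_cells()[perm, ])
  expect_identical(tab2$counts, tab$counts)

  bad <- toy_cells()
  bad$sex[3] <- NA
  expect_error(build_abundance_table(bad), "missing metadata")
})

test_that("pseudocounted fold change follows the stated arithmetic", {
  # direct arithmetic on fractions 0.02 vs 0.01
  cells <- rbind(
    data.frame(subcluster = rep(c("sA", "rest"), c(20, 980)),
               well = "cw", animal = "ca", condition = "case", sex = "M"),
    data.frame(subcluster = rep(c("sA", "rest"), c(10, 990)),
               well = "kw", animal = "ka", condition = "control", sex = "M")
  )
  tab <- build_abundance_table(cells)
  fc <- abundance_fold_change(tab, "case", "control")
  expect_equal(fc[["sA"]], (0.02 + 1e-5) / (0.01 + 1e-5), tolerance = 1e-12)
  expect_equal(fc[["sA"]], 1.99900, tolerance = 1e-4)

  # 0.001 vs 0 -> 101 exactly; 0 vs 0 -> exactly 1
  cells2 <- rbind(
    data.frame(subcluster = rep(c("sB", "rest"), c(1, 999)),
               well = "cw", animal = "ca", condition = "case", sex = "M"),
    data.frame(subcluster = rep("rest", 1000),
               well = "kw", animal = "ka", condition = "control", sex = "M")
  )
  tab2 <- build_abundance_table(cells2)
  fc2 <- abundance_fold_change(tab2, "case", "control")
  expect_equal(fc2[["sB"]], 101.0, tolerance = 1e-9)

  # pseudocount symmetry: FC(a,b) * FC(b,a) = 1
  fc_fwd <- abundance_fold_change(tab, "case", "control")
  fc_rev <- abundance_fold_change(tab, "control", "case")
  expect_equal(unname(fc_fwd * fc_rev), rep(1, length(fc_fwd)))
})

test_that("the abundance LRT flags planted shifts and swaps symmetrically", {
  cells <- simulate_abundance_cells(n_subclusters = 12,
                                    reps_per_condition = 4,
                                    cells_per_rep = 600,
                                    fold_changes = c("1" = 3), seed = 3)
  tab <- build_abundance_table(cells)
  de <- test_abundance(tab, "case", "control")
  q <- stats::setNames(de$q, de$subcluster)
  expect_lt(q[["sc01"]], 0.05)
  fc <- abundance_fold_change(tab, "case", "control")
  calls <- call_significant(fc, q, tab)
  expect_identical(calls$call[calls$subcluster == "sc01"], "up")

  # swapping case/control inverts FC and keeps q
  de_rev <- test_abundance(tab, "control", "case")
  expect_equal(de_rev$q, de$q, tolerance = 1e-6)
  fc_rev <- abundance_fold_change(tab, "control", "case")
  expect_equal(unname(fc_rev * fc), rep(1, length(fc)))
})

test_that("significance calls respect the per-sex cell floor and FC gates", {
  counts <- matrix(c(120, 60, 15, 300,
                     40, 25, 30, 100), nrow = 4,
                   dimnames = list(c("u", "n", "x", "d"), c("wM", "wF")))
  tab <- structure(list(
    counts = counts,
    replicate_meta = data.frame(well = c("wM", "wF"),
                                animal = c("a1", "a2"),
                                condition = c("case", "control"),
                                sex = c("M", "F")),
    totals = colSums(counts)
  ), class = "abundance_table")
  fc <- c(u = 2.5, n = 1.9, x = 2.5, d = 0.3)
  q <- c(u = 0.01, n = 0.001, x = 0.01, d = 0.01)
  calls <- call_significant(fc, q, tab)
  expect_identical(calls$call[calls$subcluster == "u"], "up")
  expect_identical(calls$call[calls$subcluster == "n"], "ns")     # FC floor
  expect_identical(calls$call[calls$subcluster == "x"], "excluded") # 15 < 20 in males
  expect_identical(calls$call[calls$subcluster == "d"], "down")
})

test_that("well-level and animal-level replication agree on strong effects", {
  cells <- simulate_abundance_cells(n_subclusters = 10,
                                    reps_per_condition = 4,
                                    cells_per_rep = 800,
                                    fold_changes = c("1" = 4), seed = 6)
  by_well <- build_abundance_table(cells)
  cells_an <- cells
  cells_an$well <- cells_an$animal
  by_animal <- build_abundance_table(cells_an)
  sig <- function(tab) {
    de <- test_abundance(tab, "case", "control")
    fc <- abundance_fold_change(tab, "case", "control")
    de$subcluster[de$q < 0.05 & fc[de$subcluster] > 2]
  }
  expect_identical(sig(by_well), sig(by_animal))
})
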