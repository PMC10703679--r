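test_that("score-per-million filtering normalizes and cuts at the threshold", {
  single <- data.frame(chrom = "chr1", start = 0, end = 500, score = 7)
  out <- score_per_million_filter(single, 1.3)
  expect_equal(out$spm, 1e6)

  two <- data.frame(chrom = "chr1", start = c(0, 600), end = c(500, 1100),
                    score = c(1, 3))
  out2 <- score_per_million_filter(two, 1.3)
  expect_equal(out2$spm, c(250000, 750000))
  expect_equal(nrow(out2), 2)

  many <- data.frame(chrom = "chr1", start = seq(0, 1e6, by = 1000)[1:1000],
                     end = seq(0, 1e6, by = 1000)[1:1000] + 500,
                     score = c(rep(1, 999), 999001))
  out3 <- score_per_million_filter(many, 1.3)   # spm of the small ones = 1.0
  expect_equal(nrow(out3), 1)
  expect_error(score_per_million_filter(transform(single, score = 0), 1.3),
               "zero")
})

test_that("summit windows merge per interval arithmetic and idempotently", {
  pk <- data.frame(chrom = "chr1", start = c(950, 1350), end = c(1050, 1450),
                   summit = c(1000, 1400))
  merged <- merge_summit_peaks(pk, pad = 250)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 750)
  expect_equal(merged$end, 1650)

  pk2 <- data.frame(chrom = "chr1", start = c(950, 1950), end = c(1050, 2050),
                    summit = c(1000, 2000))
  merged2 <- merge_summit_peaks(pk2, pad = 250)
  expect_equal(nrow(merged2), 2)

  again <- merge_summit_peaks(merged, pad = 250)
  expect_equal(again[c("chrom", "start", "end")],
               merged[c("chrom", "start", "end")])
  expect_warning(merge_summit_peaks(pk[, 1:3], pad = 250), "midpoint")
})

test_that("peak accessibility is binary and equals a brute-force overlap scan", {
  set.seed(4)
  peaks <- data.frame(chrom = "chr1", start = seq(0, 9000, by = 1000),
                      end = seq(0, 9000, by = 1000) + 400)
  frs <- data.frame(
    cell = sample(c("c1", "c2", "c3"), 200, replace = TRUE),
    chrom = "chr1",
    start = sample(0:9500, 200, replace = TRUE)
  )
  frs$end <- frs$start + 80
  m <- count_peak_accessibility(frs, peaks)
  expect_true(all(m@x == 1))
  # two fragments in the same peak still give 1
  dupfr <- data.frame(cell = "c1", chrom = "chr1",
                      start = c(100, 120), end = c(180, 200))
  m1 <- count_peak_accessibility(dupfr, peaks)
  expect_equal(max(m1), 1)
  # brute force
  brute <- matrix(0, nrow(peaks), 3,
                  dimnames = list(NULL, sort(unique(frs$cell))))
  for (i in seq_len(nrow(peaks))) {
    for (cell in colnames(brute)) {
      sel <- frs$cell == cell
      brute[i, cell] <- as.integer(any(
        frs$start[sel] < peaks$end[i] & frs$end[sel] > peaks$start[i]
      ))
    }
  }
  expect_equal(unname(as.matrix(m)), unname(brute))
})

test_that("differential peak filtering needs both significance and target TPM", {
  tpm <- rbind(a = c(p1 = 25, p2 = 15, p3 = 100),
               b = c(p1 = 5, p2 = 5, p3 = 50))
  de <- data.frame(feature = colnames(tpm), lrt_stat = 5, df = 1,
                   p = c(0.001, 0.001, 0.15), q = c(0.01, 0.01, 0.2),
                   flagged = FALSE, tested = TRUE)
  kept <- differential_peak_filter(de, tpm)
  expect_identical(kept$feature, "p1")
})

test_that("peak-gene linkage keeps strong positive links and prunes per peak", {
  lk <- simulate_linked_pseudocells(n_genes = 40, n_links = 5, n_decoys = 200,
                                    link_noise_sd = 0.05, seed = 11)
  res <- link_peaks_to_genes(lk$rna, lk$rna_tpm, lk$atac, lk$atac_tpm,
                             lk$annotation, seed = 1)
  truth_keys <- paste(lk$links_truth$gene, lk$links_truth$peak)
  got_keys <- paste(res$links$gene, res$links$peak)
  expect_true(all(truth_keys %in% got_keys))
  expect_true(all(res$links$pcc > 0))
  expect_true(all(abs(res$links$distance_to_tss) <= 500000))
  expect_lte(max(table(res$links$peak)), 1)          # one gene per peak

  # a perfectly anti-correlated pair is never retained
  lk2 <- lk
  g1 <- lk$links_truth$gene[1]
  p1 <- lk$links_truth$peak[1]
  lk2$atac[p1, ] <- max(lk2$atac[p1, ]) - lk2$atac[p1, ]
  lk2$atac_tpm[p1, ] <- exp(lk2$atac[p1, ]) # keep the TPM filter satisfied
  res2 <- link_peaks_to_genes(lk2$rna, lk2$rna_tpm, lk2$atac, lk2$atac_tpm,
                              lk2$annotation, seed = 1)
  expect_false(p1 %in% res2$links$peak)

  # fully permuted data yields (almost) nothing at FDR 0.01
  set.seed(2)
  atac_perm <- lk$atac[, sample(ncol(lk$atac))]
  colnames(atac_perm) <- colnames(lk$atac)
  res3 <- link_peaks_to_genes(lk$rna, lk$rna_tpm, atac_perm, lk$atac_tpm,
                              lk$annotation, seed = 3)
  expect_lte(nrow(res3$links), 2)
})

test_that("TF activity correlates with expression after rescale and z-scaling", {
  set.seed(9)
  n_cells <- 60
  labels <- rep(paste0("t", 1:6), each = 10)
  act <- rep(c(1, 3, 5, 7, 9, 11), each = 10)
  dev <- rbind(m_tf1 = act + rnorm(n_cells, 0, 0.01),
               m_flat = rep(2, n_cells))
  expr <- rbind(tf1 = 10 * act + rnorm(n_cells, 0, 0.01),
                tf2 = rnorm(n_cells, 5))
  tfm <- data.frame(tf = c("tf1", "tf2", "tf3"),
                    motif = c("m_tf1", "m_flat", "m_none"))
  res <- correlate_tf_activity(dev, expr, labels, tfm)
  expect_gt(res$pcc[["tf1"]], 0.99)
  # constant deviation vector and missing motif are skipped, listed
  expect_setequal(res$skipped, c("tf2", "tf3"))
})
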