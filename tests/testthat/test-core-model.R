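test_that("configuration defaults carry the protocol constants and validate", {
  cfg <- pipeline_config()
  expect_identical(cfg$max_barcode_mismatch, 1L)
  expect_identical(cfg$upstream_rescue_bp, 1000L)
  expect_equal(cfg$qc_max_unassigned_frac, 0.30)
  expect_identical(cfg$qc_max_umis, 20000L)
  expect_identical(cfg$qc_min_genes, 200L)
  expect_identical(cfg$n_gene_pcs, 30L)
  expect_identical(cfg$n_exon_pcs, 10L)
  expect_equal(cfg$abundance_pseudocount, 1e-5)
  expect_equal(cfg$norm_scale, 1e5)
  expect_equal(cfg$gm_rho, 1.0)
  expect_equal(cfg$atac_spm_cutoff, 1.3)
  expect_identical(cfg$atac_summit_pad_bp, 250L)
  expect_identical(cfg$cre_window_bp, 500000L)
  expect_identical(cfg$clock_pseudobulk_k, 15L)

  expect_error(pipeline_config(no_such_key = 1), "unknown configuration")
  expect_error(pipeline_config(de_fdr = 1.2), "fraction")
  expect_error(pipeline_config(qc_min_genes = -5), "integer")
})

test_that("configuration survives the flat-file round trip", {
  cfg <- pipeline_config(marker_tpm_min = 75, abundance_sex_covariate = FALSE)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_pipeline_config(cfg, path)
  back <- read_pipeline_config(path)
  expect_equal(back$marker_tpm_min, 75)
  expect_false(back$abundance_sex_covariate)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(cfg))], tolerance = 1e-12)
})

test_that("annotation enforces containment and computes strand-aware anchors", {
  g <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                  start = c(0, 500), end = c(300, 900),
                  strand = c("+", "-"))
  e <- data.frame(exon_id = c("A.e1", "B.e1"), gene_id = c("A", "B"),
                  chrom = "chr1", start = c(0, 500), end = c(100, 700),
                  strand = c("+", "-"))
  ann <- genome_annotation(g, e)
  expect_identical(unname(ann$tss[c("A", "B")]), c(0, 899))
  expect_identical(unname(ann$three_prime_end[c("A", "B")]), c(299, 500))

  e_bad <- e
  e_bad$end[1] <- 400   # exon spills past its gene
  expect_error(genome_annotation(g, e_bad), "not contained")
})

test_that("GTF import/export round-trips the annotation and converts coordinates", {
  rf <- read_fixture()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(rf$gen$annotation, path)
  back <- read_annotation_gtf(path)
  ord <- function(df) df[order(df$gene_id), c("gene_id", "chrom", "start",
                                              "end", "strand")]
  expect_equal(ord(back$genes), ord(rf$gen$annotation$genes),
               ignore_attr = TRUE)
  expect_equal(back$tss[names(rf$gen$annotation$tss)],
               rf$gen$annotation$tss)
  # raw GTF is 1-based inclusive: first gene starts at internal 0-based + 1
  raw <- read.table(path, sep = "\t")
  g1 <- raw[raw$V3 == "gene", ][1, ]
  expect_equal(g1$V4, rf$gen$annotation$genes$start[1] + 1L)
})

test_that("normalize_log applies log1p(scale * x / libsize) and flags empty cells", {
  m <- matrix(c(10, 0, 0, 5, 0, 0), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  out <- normalize_log(m)
  expect_equal(out["g1", "c1"], log1p(1e5))
  expect_equal(out["g2", "c1"], 0)                       # zero preserved
  expect_identical(attr(out, "excluded_cells"), "c3")    # flagged, not zeroed
  expect_equal(ncol(out), 2L)
  # proportional cells normalize identically
  m2 <- cbind(a = c(3, 6, 1), b = c(30, 60, 10))
  rownames(m2) <- paste0("g", 1:3)
  out2 <- normalize_log(m2)
  expect_equal(unname(out2[, "a"]), unname(out2[, "b"]))
})

test_that("tpm_aggregate sums to 1e6 per group and is order invariant", {
  m <- matrix(c(5, 5, 0, 10), nrow = 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  tpm <- tpm_aggregate(m, c("grp", "grp"))
  expect_equal(unname(tpm["grp", ]), c(250000, 750000))
  expect_equal(sum(tpm), 1e6)

  single <- tpm_aggregate(matrix(c(7, 0), 2, 1,
                                 dimnames = list(c("gA", "gB"), "c1")), "g")
  expect_equal(unname(single["g", "gA"]), 1e6)

  perm <- sample(ncol(m))
  expect_equal(tpm_aggregate(m[, perm, drop = FALSE], c("grp", "grp")[perm]),
               tpm)
  expect_error(tpm_aggregate(m, c("grp", NA)), "c2")
})

test_that("count matrices round-trip exactly through the MTX bundle", {
  cf <- counted_fixture()
  dir <- withr::local_tempdir()
  write_count_matrix(cf$cnt$gene, dir)
  back <- read_count_matrix(dir)
  expect_identical(as.matrix(back$counts), as.matrix(cf$cnt$gene$counts))
  expect_identical(back$cells, cf$cnt$gene$cells)
  expect_identical(back$features, cf$cnt$gene$features)
  expect_equal(back$per_cell_stats$total_reads,
               cf$cnt$gene$per_cell_stats$total_reads)
})

test_that("per-cell statistics must satisfy read conservation", {
  st <- data.frame(cell = "c1", total_reads = 10, assigned = 5,
                   ambiguous = 2, discarded = 2, duplicates = 2)
  m <- matrix(1L, 1, 1, dimnames = list("g", "c1"))
  expect_error(count_matrix(m, per_cell_stats = st), "conservation")
  st$duplicates <- 1
  cm <- count_matrix(m, per_cell_stats = st)
  expect_equal(cm$per_cell_stats$unassigned_frac, 0.4)
})
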