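test_that("combined embedding concatenates gene and exon PC blocks", {
  sim <- simulate_cluster_counts(n_cells = 120, n_genes = 40,
                                 n_clusters = 3, seed = 2)
  gn <- as.matrix(normalize_log(sim$gene))
  en <- as.matrix(normalize_log(sim$exon))
  cfg <- pipeline_config(n_gene_pcs = 10L, n_exon_pcs = 5L)
  emb <- combined_pca_embedding(gn, en, cfg, seed = 1, umap = FALSE)
  expect_identical(emb$provenance$n_gene_pcs + emb$provenance$n_exon_pcs,
                   ncol(emb$coords_pca))
  expect_true(all(startsWith(colnames(emb$coords_pca)[1:emb$provenance$n_gene_pcs],
                             "genePC")))

  # all-zero exon block degrades to the gene-only embedding
  emb_zero <- combined_pca_embedding(gn, en * 0, cfg, seed = 1, umap = FALSE)
  emb_gene <- combined_pca_embedding(gn, NULL, cfg, seed = 1, umap = FALSE)
  expect_identical(emb_zero$provenance$n_exon_pcs, 0L)
  expect_equal(emb_zero$coords_pca, emb_gene$coords_pca)

  # a rank-2 gene matrix cannot yield more than 2 gene PCs
  lowrank <- outer(c(1, 2, 3, 4), rep(1, 120)) +
    outer(c(0, 1, 0, 1), rep(c(0, 5), 60))
  dimnames(lowrank) <- list(paste0("g", 1:4), colnames(gn))
  emb_lr <- combined_pca_embedding(lowrank, NULL, cfg, seed = 1, umap = FALSE)
  expect_lte(emb_lr$provenance$n_gene_pcs, 2L)

  expect_error(combined_pca_embedding(gn, en[, 1:10], cfg), "same cells")
})

test_that("exon-aware clustering separates exon-usage twins that gene space cannot", {
  sim <- simulate_cluster_counts(n_cells = 300, n_genes = 100,
                                 n_clusters = 3, nb_dispersion = 0.2, seed = 1)
  # twins share gene-level means exactly
  expect_identical(sim$gene_means[, 2], sim$gene_means[, 3])
  gn <- normalize_log(sim$gene)
  en <- normalize_log(sim$exon)
  cfg <- pipeline_config()
  both <- combined_pca_embedding(gn, en, cfg, seed = 1, umap = FALSE)
  gene <- combined_pca_embedding(gn, NULL, cfg, seed = 1, umap = FALSE)
  ari_both <- adjusted_rand(cluster_cells(both, seed = 1), sim$clusters)
  ari_gene <- adjusted_rand(cluster_cells(gene, seed = 1), sim$clusters)
  expect_gt(ari_both, 0.9)
  expect_lt(ari_gene, 0.7)

  # silhouette of the twin split, computed both ways
  twins <- sim$clusters >= 2
  sil <- function(coords) {
    d <- as.matrix(dist(coords[twins, , drop = FALSE]))
    lab <- sim$clusters[twins]
    mean(sapply(seq_along(lab), function(i) {
      a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
      b <- mean(d[i, lab != lab[i]])
      (b - a) / max(a, b)
    }))
  }
  expect_gt(sil(both$coords_pca), 0)
})

test_that("clustering is deterministic and finds well-separated blobs", {
  sim <- simulate_cluster_counts(n_cells = 240, n_genes = 60,
                                 n_clusters = 2, seed = 4)
  gn <- normalize_log(sim$gene)
  emb <- combined_pca_embedding(gn, NULL, pipeline_config(), seed = 1,
                                umap = FALSE)
  l1 <- cluster_cells(emb, seed = 1)
  l2 <- cluster_cells(emb, seed = 1)
  expect_identical(l1, l2)
  expect_gt(adjusted_rand(l1, sim$clusters), 0.9)
  # reseeding keeps the same partition on clean blobs
  expect_gte(adjusted_rand(cluster_cells(emb, seed = 7), l1), 0.9)
  expect_warning(cluster_cells(emb$coords_pca[1:5, , drop = FALSE]),
                 "single cluster")
})

test_that("indistinct subclusters merge by the centroid-distance rule", {
  set.seed(3)
  blob <- function(cx, cy, n = 40, sd = 0.5) {
    cbind(rnorm(n, cx, sd), rnorm(n, cy, sd))
  }
  # four labels, two of them coincident
  coords <- rbind(blob(0, 0), blob(10, 0), blob(20, 0), blob(20, 0.05))
  rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
  labels <- rep(1:4, each = 40)
  m <- merge_indistinct_subclusters(labels, coords, min_sep = 1)
  expect_equal(nrow(m$merge_log), 1)
  expect_equal(length(unique(m$labels)), 3)
  # far-apart clusters stay untouched
  far <- rbind(blob(0, 0, sd = 0.1), blob(100, 0, sd = 0.1))
  m2 <- merge_indistinct_subclusters(rep(1:2, each = 40), far, min_sep = 1)
  expect_equal(nrow(m2$merge_log), 0)
})

test_that("the NB likelihood-ratio test detects planted effects and stays calibrated", {
  set.seed(21)
  n <- 120
  grp <- factor(rep(c("a", "b"), each = n / 2))
  null_counts <- matrix(rpois(200 * n, 8), 200, n)
  de0 <- de_test_lrt(null_counts, grp)
  expect_lte(mean(de0$q < 0.05, na.rm = TRUE), 0.05)

  # planted 10-fold feature is found at q < 0.01
  planted <- null_counts
  planted[1, grp == "b"] <- rpois(n / 2, 80)
  de1 <- de_test_lrt(planted, grp)
  expect_lt(de1$q[1], 0.01)
  expect_gte(min(de1$lrt_stat, na.rm = TRUE), 0)

  # a covariate that exactly encodes the group leaves nothing to test:
  # full and reduced models coincide, LRT 0, p 1
  cov <- data.frame(dup = as.integer(grp == "b"))
  de2 <- de_test_lrt(null_counts[1:5, , drop = FALSE], grp, covariates = cov)
  expect_true(all(abs(de2$lrt_stat) < 1e-6))
  expect_true(all(de2$p > 0.999))
})

test_that("BH adjustment equals its brute-force definition", {
  set.seed(8)
  for (m in c(1, 7, 200)) {
    p <- runif(m)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # q is monotone in p within a family
  de <- data.frame(p = sort(runif(50)))
  q <- p.adjust(de$p, "BH")
  expect_true(all(diff(q) >= -1e-15))
})

test_that("marker selection applies the mouse and human cutoff sets", {
  tpm <- rbind(
    t1 = c(f1 = 100, f2 = 100, f3 = 49, f4 = 300),
    t2 = c(f1 = 30, f2 = 52, f3 = 10, f4 = 10)
  )
  de <- data.frame(feature = colnames(tpm),
                   lrt_stat = 10, df = 1,
                   p = c(0.001, 0.001, 0.001, 0.2),
                   q = c(0.01, 0.01, 0.01, 0.4),
                   flagged = FALSE, tested = TRUE)
  mouse <- select_markers(de, tpm, "mouse_marker")
  human <- select_markers(de, tpm, "human_de")
  # f1: FC ~3.2, TPM 100 -> kept in both
  expect_true("f1" %in% mouse$feature && "f1" %in% human$feature)
  # f2: FC (101/53) ~1.9 -> human only (1.5 < 1.9 < 2)
  expect_false("f2" %in% mouse$feature)
  expect_true("f2" %in% human$feature)
  # f3: below the TPM floor in the top group
  expect_false("f3" %in% mouse$feature || "f3" %in% human$feature)
  # f4: fails the q cutoff despite a huge fold change
  expect_false("f4" %in% mouse$feature)
  expect_error(select_markers(de, tpm[1, , drop = FALSE], "mouse_marker"),
               "second rank")
})
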