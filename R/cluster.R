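#' Combined gene + exon PCA embedding
#'
#' Exon-aware embedding for subclustering: the first \code{n_gene_pcs}
#' principal components of the log-normalized gene matrix are concatenated
#' with the first \code{n_exon_pcs} components of the log-normalized exon
#' matrix (block order [gene PCs | exon PCs]). Exon usage differences that
#' leave gene-level totals unchanged are invisible to the gene block but
#' separate cells in the exon block. A rank-deficient block contributes
#' only its rank, recorded in the provenance. A 2D UMAP of the combined
#' space is attached for cluster merging and visualization.
#'
#' @param gene_norm,exon_norm log-normalized matrices, features x cells,
#'   same cells in the same order (see \code{\link{normalize_log}}).
#'   \code{exon_norm} may be NULL or all-zero, in which case the embedding
#'   reduces to the gene block alone.
#' @param config a \code{\link{pipeline_config}} (n_gene_pcs, n_exon_pcs).
#' @param seed RNG seed for PCA initialization and UMAP.
#' @param umap logical; compute 2D coordinates (default TRUE).
#' @return list of class \code{sci_embedding}: \code{coords_pca}
#'   (cells x kept PCs), \code{coords_2d} (cells x 2 or NULL),
#'   \code{provenance}.
#' @export
combined_pca_embedding <- function(gene_norm, exon_norm = NULL,
                                   config = pipeline_config(), seed = 1L,
                                   umap = TRUE) {
  if (!is.null(exon_norm) && !identical(colnames(gene_norm), colnames(exon_norm))) {
    stop("gene and exon matrices must cover the same cells in the same order")
  }
  if (ncol(gene_norm) < 2L) {
    stop("embedding needs at least 2 cells (got ", ncol(gene_norm), ")")
  }
  gene_pcs <- .pca_block(gene_norm, config$n_gene_pcs, seed)
  exon_pcs <- if (is.null(exon_norm)) NULL else .pca_block(exon_norm, config$n_exon_pcs, seed)
  coords <- cbind(gene_pcs, exon_pcs)
  colnames(coords) <- c(
    paste0("genePC", seq_len(ncol(gene_pcs))),
    if (!is.null(exon_pcs) && ncol(exon_pcs)) paste0("exonPC", seq_len(ncol(exon_pcs)))
  )
  rownames(coords) <- colnames(gene_norm)
  coords_2d <- NULL
  if (umap) {
    set.seed(seed)
    nn <- min(15L, nrow(coords) - 1L)
    coords_2d <- uwot::umap(coords, n_neighbors = nn, n_threads = 1,
                            n_sgd_threads = 0, seed = seed)
    rownames(coords_2d) <- rownames(coords)
  }
  structure(list(
    coords_pca = coords, coords_2d = coords_2d,
    provenance = list(n_gene_pcs = ncol(gene_pcs),
                      n_exon_pcs = if (is.null(exon_pcs)) 0L else ncol(exon_pcs),
                      seed = seed)
  ), class = "sci_embedding")
}

# centered PCA of a features x cells matrix -> cells x k scores
.pca_block <- function(x, k, seed) {
  x <- as.matrix(x)
  xt <- t(x)                         # cells x features
  xt <- sweep(xt, 2L, colMeans(xt))
  r <- min(dim(xt)) - 1L             # conservative rank bound after centering
  k_eff <- max(0L, min(k, r))
  if (k_eff == 0L || all(xt == 0)) {
    return(matrix(0, nrow(xt), 0L))
  }
  if (k_eff < min(dim(xt)) / 3 && min(dim(xt)) > 50L) {
    set.seed(seed)
    sv <- irlba::irlba(xt, nv = k_eff)
    scores <- sv$u %*% diag(sv$d, k_eff, k_eff)
  } else {
    sv <- svd(xt, nu = k_eff, nv = 0L)
    scores <- sv$u %*% diag(sv$d[seq_len(k_eff)], k_eff, k_eff)
  }
  # drop numerically null components (true rank < k)
  keep <- .pca_sv_keep(scores)
  scores[, keep, drop = FALSE]
}

.pca_sv_keep <- function(scores) {
  norms <- sqrt(colSums(scores^2))
  norms > max(norms) * 1e-8
}

#' Louvain clustering of cells in an embedding
#'
#' Builds a shared-nearest-neighbor graph (Jaccard-weighted k-nearest
#' neighbors in PC space) and partitions it with Louvain community
#' detection. Deterministic for a fixed seed. Fewer than 10 cells give a
#' single cluster with a warning.
#'
#' @param embedding a \code{sci_embedding} or a cells x dims matrix.
#' @param resolution Louvain resolution parameter.
#' @param k neighbors for the SNN graph.
#' @param seed RNG seed.
#' @return integer cluster labels named by cell.
#' @export
cluster_cells <- function(embedding, resolution = 1.0, k = 20L, seed = 1L) {
  coords <- if (inherits(embedding, "sci_embedding")) embedding$coords_pca else embedding
  n <- nrow(coords)
  if (n < 10L) {
    warning("fewer than 10 cells; returning a single cluster")
    return(stats::setNames(rep(1L, n), rownames(coords)))
  }
  k <- min(k, n - 1L)
  nn <- RANN::nn2(coords, k = k + 1L)$nn.idx[, -1L, drop = FALSE]
  # SNN: Jaccard similarity of neighbor sets for each kNN edge
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  nb_list <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  w <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nb_list[[edges[e, 1L]]]
    b <- nb_list[[edges[e, 2L]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  keep <- w > 1 / 15
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::simplify(igraph::set_edge_attr(g, "weight", value = w[keep]),
                        edge.attr.comb = "max")
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(as.integer(igraph::membership(comm)), rownames(coords))
}

#' Merge subclusters not separable in 2D embedding space
#'
#' Operationalizes the manual "merge subclusters that are not readily
#' distinguishable in UMAP space" step: iteratively merges the closest
#' pair of clusters whose centroid distance is below
#' \code{min_sep} x (pooled median within-cluster radius of the pair),
#' until no pair qualifies.
#'
#' @param labels cluster labels (any type), one per cell.
#' @param coords_2d cells x 2 embedding coordinates.
#' @param min_sep separation multiplier (default 1).
#' @return list with \code{labels} (merged, renumbered 1..K) and
#'   \code{merge_log} data.frame (from, into, distance, radius).
#' @export
merge_indistinct_subclusters <- function(labels, coords_2d, min_sep = 1.0) {
  labels <- as.character(labels)
  merge_log <- data.frame(from = character(), into = character(),
                          distance = numeric(), radius = numeric(),
                          stringsAsFactors = FALSE)
  repeat {
    cl <- sort(unique(labels))
    if (length(cl) < 2L) break
    cent <- t(vapply(cl, function(c) colMeans(coords_2d[labels == c, , drop = FALSE]),
                     numeric(ncol(coords_2d))))
    radii <- lapply(cl, function(c) {
      d <- coords_2d[labels == c, , drop = FALSE]
      sqrt(rowSums(sweep(d, 2L, colMeans(d))^2))
    })
    names(radii) <- cl
    best <- NULL
    for (a in seq_along(cl)) {
      for (b in seq_along(cl)) {
        if (b <= a) next
        dist_ab <- sqrt(sum((cent[a, ] - cent[b, ])^2))
        rad <- stats::median(c(radii[[a]], radii[[b]]))
        if (rad == 0) rad <- .Machine$double.eps
        if (dist_ab < min_sep * rad &&
            (is.null(best) || dist_ab < best$distance)) {
          best <- list(a = cl[a], b = cl[b], distance = dist_ab, radius = rad)
        }
      }
    }
    if (is.null(best)) break
    labels[labels == best$b] <- best$a
    merge_log <- rbind(merge_log, data.frame(
      from = best$b, into = best$a, distance = best$distance,
      radius = best$radius, stringsAsFactors = FALSE))
  }
  list(labels = stats::setNames(as.integer(factor(labels)), rownames(coords_2d)),
       merge_log = merge_log)
}
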