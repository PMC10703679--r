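#' Filter genes for module discovery
#'
#' On the library-size-normalized subcluster pseudobulk (linear scale;
#' the log transform is applied afterwards for the embedding, since a
#' ratio of log values would penalize highly expressed genes), keeps
#' genes that are expressed (maximum across subclusters at least
#' \code{gm_min_expr}) and variable (fold change between the maximum
#' subcluster and the median across subclusters at least
#' \code{gm_min_fc}). A zero median would make the ratio undefined; it is
#' replaced by the smallest positive value in the matrix, so strongly
#' expressed genes silent in most subclusters are retained — the filter's
#' intent.
#'
#' @param pseudobulk genes x subclusters normalized matrix (linear
#'   scale).
#' @param config a \code{\link{pipeline_config}}.
#' @return the filtered matrix (subset of rows).
#' @export
filter_module_genes <- function(pseudobulk, config = pipeline_config()) {
  x <- as.matrix(pseudobulk)
  mx <- apply(x, 1L, max)
  med <- apply(x, 1L, stats::median)
  eps <- min(x[x > 0])
  fc <- mx / pmax(med, eps)
  keep <- mx >= config$gm_min_expr & fc >= config$gm_min_fc
  x[keep, , drop = FALSE]
}

#' Embed genes in 2D with UMAP
#'
#' Genes (rows) are embedded by their expression profiles across
#' subclusters with cosine distance, \code{min_dist} 0.01 and 30
#' neighbors; deterministic for a fixed seed.
#'
#' @param x genes x subclusters matrix (filtered).
#' @param config a \code{\link{pipeline_config}}.
#' @param seed RNG seed.
#' @return genes x 2 coordinate matrix with a \code{"params"} attribute.
#' @export
embed_genes <- function(x, config = pipeline_config(), seed = 1L) {
  x <- as.matrix(x)
  nn <- config$gm_umap_n_neighbors
  if (nrow(x) < nn) {
    stop("only ", nrow(x), " genes retained; need at least ", nn,
         " for the UMAP neighborhood size")
  }
  set.seed(seed)
  # PCA initialization: deterministic and stable when the neighbor graph
  # has disconnected components (spectral init scatters them)
  coords <- uwot::umap(x, metric = "cosine", min_dist = config$gm_umap_min_dist,
                       n_neighbors = nn, n_threads = 1, n_sgd_threads = 0,
                       seed = seed, init = "pca")
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("UMAP1", "UMAP2")
  attr(coords, "params") <- list(metric = "cosine",
                                 min_dist = config$gm_umap_min_dist,
                                 n_neighbors = nn, seed = seed)
  coords
}

#' Density-peak clustering of 2D gene coordinates
#'
#' Rodriguez-Laio density-peak clustering: each point's local density
#' \eqn{\rho_i = \sum_{j \ne i} \exp(-(d_{ij}/d_c)^2)} uses a Gaussian
#' kernel with cutoff \eqn{d_c} fixed at the 2nd percentile of pairwise
#' distances; \eqn{\delta_i} is the distance to the nearest point of
#' higher density (the global density peak takes the maximum pairwise
#' distance). Points with \eqn{\rho > \rho_{min}} and
#' \eqn{\delta > \delta_{min}} are module centers; every other point
#' joins the module of its nearest higher-density neighbor, in
#' decreasing-density order. Density ties are broken by point index so
#' the assignment is deterministic and order-stable.
#'
#' @param coords points x 2 matrix.
#' @param rho_min,delta_min center thresholds (protocol: 1 and 1).
#' @return list of class \code{gene_module_result}: \code{module} (integer
#'   per point, named), \code{centers}, \code{rho}, \code{delta},
#'   \code{dc}, \code{coords}.
#' @export
density_cluster <- function(coords, rho_min = 1.0, delta_min = 1.0) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(all(is.finite(coords)), n >= 2L)
  d <- as.matrix(stats::dist(coords))
  dc <- stats::quantile(d[upper.tri(d)], probs = 0.02, names = FALSE)
  if (dc == 0) dc <- min(d[upper.tri(d)][d[upper.tri(d)] > 0], na.rm = TRUE)
  rho <- rowSums(exp(-(d / dc)^2)) - 1            # exclude self term
  # order by decreasing density, index-stable for ties
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1L]] <- max(d)
  nn_higher[ord[1L]] <- ord[1L]
  for (k in 2:n) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1L)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    nn_higher[i] <- j
  }
  centers <- which(rho > rho_min & delta > delta_min)
  if (length(centers) == 0L) {
    warning("no density peak passed both thresholds; returning one module")
    centers <- ord[1L]
  }
  module <- integer(n)
  module[centers] <- seq_along(centers)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (module[i] == 0L) module[i] <- module[nn_higher[i]]
  }
  names(module) <- rownames(coords)
  structure(list(module = module, centers = centers, rho = rho,
                 delta = delta, dc = dc, coords = coords),
            class = "gene_module_result")
}

#' @export
print.gene_module_result <- function(x, ...) {
  cat("<gene_module_result>", length(unique(x$module)), "modules over",
      length(x$module), "genes (dc =", format(x$dc, digits = 3), ")\n")
  invisible(x)
}

#' Discover gene modules end to end
#'
#' Convenience wrapper: subcluster pseudobulk aggregation and
#' normalization, expression/variance filtering, gene UMAP, density-peak
#' clustering.
#'
#' @param cm gene-level \code{\link{count_matrix}} (or matrix).
#' @param subclusters subcluster label per cell.
#' @param config a \code{\link{pipeline_config}}.
#' @param seed RNG seed.
#' @return a \code{gene_module_result} (see \code{\link{density_cluster}}).
#' @export
find_gene_modules <- function(cm, subclusters, config = pipeline_config(),
                              seed = 1L) {
  x <- if (inherits(cm, "count_matrix")) cm$counts else cm
  agg <- .aggregate_columns(x, as.character(subclusters))
  norm <- sweep(agg, 2L, colSums(agg), `/`) * config$norm_scale
  filt <- filter_module_genes(norm, config)
  coords <- embed_genes(log1p(filt), config, seed)
  density_cluster(coords, config$gm_rho, config$gm_delta)
}
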