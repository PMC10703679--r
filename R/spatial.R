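#' Cell-type signature matrix for spatial deconvolution
#'
#' Aggregates UMI counts per cell-type label, normalizes each aggregate by
#' its library size, multiplies by 1e5 and log-transforms with a
#' pseudocount — the same normalization applied to the spatial spots being
#' deconvolved. Doubling all counts of a type leaves its signature
#' unchanged.
#'
#' @param cm a \code{\link{count_matrix}} or features x cells matrix.
#' @param labels cell-type label per cell.
#' @param config a \code{\link{pipeline_config}} (norm_scale).
#' @param features optional feature subset (e.g. marker genes) used for the
#'   signatures; defaults to all features.
#' @return features x cell-types matrix with attribute \code{"n_cells"}
#'   (cells aggregated per column). Labels with zero cells are dropped
#'   with a warning.
#' @export
build_signature_matrix <- function(cm, labels, config = pipeline_config(),
                                   features = NULL) {
  x <- if (inherits(cm, "count_matrix")) cm$counts else cm
  stopifnot(length(labels) == ncol(x))
  n_cells <- table(labels)
  if (any(n_cells == 0)) {
    warning("dropping empty label(s): ",
            paste(names(n_cells)[n_cells == 0], collapse = ", "))
  }
  agg <- .aggregate_columns(x, as.character(labels))
  if (!is.null(features)) agg <- agg[features, , drop = FALSE]
  sig <- as.matrix(normalize_log(agg, scale = config$norm_scale))
  attr(sig, "n_cells") <- as.integer(n_cells[colnames(sig)])
  sig
}

#' Non-negative least-squares deconvolution of spatial spots
#'
#' Expresses each spot's normalized expression as a non-negative
#' combination of cell-type signatures: per spot,
#' \eqn{\min_{w \ge 0} \|S w - y\|_2} solved by the Lawson-Hanson
#' active-set method. The Karush-Kuhn-Tucker conditions are verified at
#' every solution (gradient non-negative on the zero set, complementary
#' slackness) and the worst violation is reported.
#'
#' @param spots features x spots matrix, normalized like the signatures.
#' @param signatures features x cell-types matrix
#'   (\code{\link{build_signature_matrix}}); must share the spot feature
#'   set.
#' @return list of class \code{spot_deconvolution}: \code{weights}
#'   (spots x cell-types, >= 0), \code{proportions} (rows normalized to 1;
#'   zero rows stay zero), \code{residuals} (per-spot residual norm),
#'   \code{kkt} (per-spot worst KKT violation).
#' @export
nnls_deconvolve <- function(spots, signatures) {
  if (!identical(rownames(spots), rownames(signatures))) {
    d1 <- setdiff(rownames(spots), rownames(signatures))
    d2 <- setdiff(rownames(signatures), rownames(spots))
    stop("feature sets differ between spots and signatures: ",
         paste(utils::head(c(d1, d2), 5L), collapse = ", "))
  }
  S <- as.matrix(signatures)
  Y <- as.matrix(spots)
  k <- ncol(S)
  n <- ncol(Y)
  W <- matrix(0, n, k, dimnames = list(colnames(Y), colnames(S)))
  resid <- kkt <- numeric(n)
  for (j in seq_len(n)) {
    y <- Y[, j]
    if (all(y == 0)) {
      resid[j] <- 0
      kkt[j] <- 0
      next
    }
    fit <- pracma::lsqnonneg(S, y)
    w <- fit$x
    W[j, ] <- w
    r <- S %*% w - y
    resid[j] <- sqrt(sum(r^2))
    g <- drop(crossprod(S, r))                    # gradient of 0.5*||Sw-y||^2
    kkt[j] <- max(0, -g[w <= 1e-12], abs(g[w > 1e-12]), na.rm = TRUE)
  }
  rs <- rowSums(W)
  P <- W
  P[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(weights = W, proportions = P, residuals = resid, kkt = kkt),
            class = "spot_deconvolution")
}

#' @export
print.spot_deconvolution <- function(x, ...) {
  cat("<spot_deconvolution>", nrow(x$weights), "spots x", ncol(x$weights),
      "cell types; max KKT violation",
      format(max(x$kkt), digits = 3), "\n")
  invisible(x)
}
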