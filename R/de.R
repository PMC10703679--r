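#' Negative-binomial likelihood-ratio differential test
#'
#' Per-feature NB generalized linear model with log link and a per-sample
#' offset (log library size by default), testing the full model
#' \code{counts ~ group + covariates} against the reduced model
#' \code{counts ~ covariates} with a chi-squared likelihood-ratio test.
#' The dispersion is moment-estimated per feature from Pearson residuals of
#' a Poisson fit of the full model; features whose counts are
#' underdispersed fall back to a near-Poisson fit. q-values are
#' Benjamini-Hochberg over tested features. Features detected in fewer
#' than \code{min_detect} samples are excluded and reported with NA
#' statistics. Degenerate fits are flagged, never fatal.
#'
#' @param counts integer matrix, features x samples (dense or sparse).
#' @param groups factor of length ncol(counts); the tested effect.
#' @param covariates optional data.frame of per-sample covariates (e.g.
#'   sex) adjusted for in both models.
#' @param offset per-sample offset on the log scale; default
#'   \code{log(colSums(counts))}.
#' @param min_detect minimum number of samples with a nonzero count for a
#'   feature to be tested (default 1).
#' @return data.frame: feature, lrt_stat, df, p, q, flagged.
#' @export
de_test_lrt <- function(counts, groups, covariates = NULL, offset = NULL,
                        min_detect = 1L) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("at least two groups required")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- ncol(counts)
  if (is.null(offset)) {
    libsize <- colSums(counts)
    if (any(libsize == 0)) stop("sample(s) with zero library size")
    offset <- log(libsize)
  }
  dat <- data.frame(group = groups)
  full_rhs <- "group"
  red_rhs <- "1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    dat <- cbind(dat, covariates)
    full_rhs <- paste(c("group", names(covariates)), collapse = " + ")
    red_rhs <- paste(names(covariates), collapse = " + ")
  }
  f_full <- stats::as.formula(paste("y ~", full_rhs))
  f_red <- stats::as.formula(paste("y ~", red_rhs))

  nfeat <- nrow(counts)
  lrt <- p <- rep(NA_real_, nfeat)
  dfs <- rep(NA_integer_, nfeat)
  flagged <- rep(FALSE, nfeat)
  tested <- rowSums(counts > 0) >= min_detect
  for (i in which(tested)) {
    dat$y <- counts[i, ]
    res <- tryCatch({
      theta <- .moment_theta(dat$y, dat, f_full, offset)
      fam <- MASS::negative.binomial(theta = theta)
      fit_full <- suppressWarnings(
        stats::glm(f_full, family = fam, data = dat, offset = offset))
      fit_red <- suppressWarnings(
        stats::glm(f_red, family = fam, data = dat, offset = offset))
      stat <- max(0, as.numeric(2 * (stats::logLik(fit_full) - stats::logLik(fit_red))))
      ddf <- fit_red$df.residual - fit_full$df.residual
      list(stat = stat, ddf = ddf,
           p = if (ddf > 0) stats::pchisq(stat, ddf, lower.tail = FALSE) else 1)
    }, error = function(e) NULL)
    if (is.null(res)) {
      flagged[i] <- TRUE
    } else {
      lrt[i] <- res$stat
      dfs[i] <- res$ddf
      p[i] <- res$p
    }
  }
  q <- rep(NA_real_, nfeat)
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(
    feature = if (is.null(rownames(counts))) as.character(seq_len(nfeat)) else rownames(counts),
    lrt_stat = lrt, df = dfs, p = p, q = q,
    flagged = flagged, tested = tested,
    stringsAsFactors = FALSE
  )
}

# moment estimate of the NB size parameter from Pearson residuals of a
# Poisson fit; underdispersion clips to a near-Poisson theta
.moment_theta <- function(y, dat, formula, offset, theta_max = 1e8) {
  pois <- suppressWarnings(
    stats::glm(formula, family = stats::poisson(), data = dat, offset = offset))
  mu <- stats::fitted(pois)
  dfr <- max(1L, pois$df.residual)
  excess <- sum(((y - mu)^2 - mu) / mu^2) / dfr   # estimate of 1/theta
  if (!is.finite(excess) || excess <= 1 / theta_max) return(theta_max)
  1 / excess
}

#' Fold change between first- and second-ranked groups
#'
#' For each feature, the ratio of the highest group-level expression to the
#' second highest, plus which group ranks first — the quantities the marker
#' cutoffs are phrased in.
#'
#' @param tpm groups x features matrix (see \code{\link{tpm_aggregate}}).
#' @param pseudocount added to numerator and denominator so features absent
#'   from the runner-up group get a finite ratio (default 1).
#' @return data.frame: feature, first_group, tpm_first, tpm_second,
#'   fc_first_vs_second.
#' @export
rank_fold_change <- function(tpm, pseudocount = 1) {
  if (nrow(tpm) < 2L) stop("need at least two groups to rank (no second rank)")
  first_i <- apply(tpm, 2L, which.max)
  tpm_first <- tpm[cbind(first_i, seq_len(ncol(tpm)))]
  tpm2 <- tpm
  tpm2[cbind(first_i, seq_len(ncol(tpm)))] <- -Inf
  second_i <- apply(tpm2, 2L, which.max)
  tpm_second <- tpm[cbind(second_i, seq_len(ncol(tpm)))]
  data.frame(
    feature = colnames(tpm),
    first_group = rownames(tpm)[first_i],
    tpm_first = tpm_first,
    tpm_second = tpm_second,
    fc_first_vs_second = (tpm_first + pseudocount) / (tpm_second + pseudocount),
    stringsAsFactors = FALSE
  )
}

#' Select cell-type markers or condition DE genes
#'
#' Applies the protocol's cutoffs to a differential-test table joined with
#' group-level expression ranks. \code{mode = "mouse_marker"} keeps
#' features with q < 0.05, over twofold difference between the first- and
#' second-ranked groups, and TPM > 50 in the first-ranked group.
#' \code{mode = "human_de"} keeps q < 0.05, fold change > 1.5 between the
#' highest and second condition, and TPM > 50 in the highest condition.
#'
#' @param de data.frame from \code{\link{de_test_lrt}}.
#' @param tpm groups x features matrix from \code{\link{tpm_aggregate}}.
#' @param mode "mouse_marker" or "human_de".
#' @param config a \code{\link{pipeline_config}}.
#' @return data.frame of kept features with q, fold change, first group
#'   and its TPM.
#' @export
select_markers <- function(de, tpm, mode = c("mouse_marker", "human_de"),
                           config = pipeline_config()) {
  mode <- match.arg(mode)
  fc_min <- if (mode == "mouse_marker") config$marker_fc_min else config$human_de_fc_min
  rk <- rank_fold_change(tpm)
  m <- match(de$feature, rk$feature)
  if (anyNA(m)) stop("feature sets of DE table and TPM matrix differ")
  tab <- cbind(de, rk[m, c("first_group", "tpm_first", "fc_first_vs_second")])
  keep <- !is.na(tab$q) & tab$q < config$de_fdr &
    tab$fc_first_vs_second > fc_min &
    tab$tpm_first > config$marker_tpm_min
  rownames(tab) <- NULL
  tab[keep, , drop = FALSE]
}
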