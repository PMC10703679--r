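#' Subcluster-by-replicate cell count table
#'
#' Each RT well is a replicate from one animal; the table counts cells per
#' subcluster per replicate, with explicit zeros, alongside replicate-level
#' metadata (animal, condition, sex) and per-replicate totals.
#'
#' @param cell_meta data.frame with one row per cell and columns
#'   \code{subcluster}, \code{well}, \code{condition}, \code{sex},
#'   \code{animal}. Missing values are an error.
#' @return object of class \code{abundance_table}: \code{counts}
#'   (subcluster x replicate integer matrix), \code{replicate_meta},
#'   \code{totals}.
#' @export
build_abundance_table <- function(cell_meta) {
  need <- c("subcluster", "well", "condition", "sex", "animal")
  stopifnot(all(need %in% names(cell_meta)))
  if (anyNA(cell_meta[need])) {
    bad <- which(rowSums(is.na(cell_meta[need])) > 0)[1L]
    stop("cell with missing metadata at row ", bad)
  }
  counts <- table(subcluster = as.character(cell_meta$subcluster),
                  replicate = as.character(cell_meta$well))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  meta <- unique(cell_meta[c("well", "animal", "condition", "sex")])
  if (anyDuplicated(meta$well)) {
    stop("replicate well(s) map to more than one condition/sex/animal")
  }
  meta <- meta[match(colnames(counts), meta$well), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, replicate_meta = meta,
                 totals = colSums(counts)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>", nrow(x$counts), "subclusters x", ncol(x$counts),
      "replicates;", sum(x$counts), "cells\n")
  invisible(x)
}

#' Pseudocounted abundance fold change between conditions
#'
#' Per subcluster: cells are normalized to each condition's total cell
#' count, and the case/control ratio of those fractions is taken after
#' adding a small pseudocount (1e-5) to both, which damps the effect of
#' very small clusters and keeps FC(a,b) * FC(b,a) = 1.
#'
#' @param tab an \code{\link{build_abundance_table}} result.
#' @param case,control condition labels.
#' @param pseudocount added to both fractions (default 1e-5).
#' @return named numeric vector of fold changes per subcluster.
#' @export
abundance_fold_change <- function(tab, case, control, pseudocount = 1e-5) {
  cond <- tab$replicate_meta$condition
  if (!case %in% cond || !control %in% cond) stop("condition absent from table")
  frac <- function(cc) {
    cols <- cond == cc
    tot <- sum(tab$counts[, cols, drop = FALSE])
    if (tot == 0) stop("zero total cells in condition ", cc)
    rowSums(tab$counts[, cols, drop = FALSE]) / tot
  }
  (frac(case) + pseudocount) / (frac(control) + pseudocount)
}

#' Likelihood-ratio test for differential subcluster abundance
#'
#' Per subcluster, an NB-GLM likelihood-ratio test of replicate-level cell
#' counts with an offset of log(replicate total cells), so the tested
#' quantity is the subcluster's fraction of the population:
#' full model \code{count ~ condition (+ sex)} against reduced
#' \code{~ (sex)}. BH q-values over subclusters; an all-zero subcluster is
#' flagged with q = 1.
#'
#' @param tab an \code{abundance_table}.
#' @param case,control the two conditions compared (others are dropped).
#' @param config a \code{\link{pipeline_config}};
#'   \code{abundance_sex_covariate} controls the sex adjustment.
#' @return data.frame: subcluster, lrt_stat, p, q, flagged.
#' @export
test_abundance <- function(tab, case, control, config = pipeline_config()) {
  keep <- tab$replicate_meta$condition %in% c(case, control)
  if (sum(tab$replicate_meta$condition[keep] == case) < 2L ||
      sum(tab$replicate_meta$condition[keep] == control) < 2L) {
    stop("need at least two replicates per condition")
  }
  counts <- tab$counts[, keep, drop = FALSE]
  meta <- tab$replicate_meta[keep, , drop = FALSE]
  offset <- log(tab$totals[keep])
  groups <- factor(meta$condition, levels = c(control, case))
  covars <- if (isTRUE(config$abundance_sex_covariate) &&
                length(unique(meta$sex)) > 1L) {
    data.frame(sex = factor(meta$sex))
  } else NULL
  zero <- rowSums(counts) == 0
  de <- de_test_lrt(counts, groups, covariates = covars, offset = offset,
                    min_detect = 1L)
  de$q[zero] <- 1
  de$p[zero] <- 1
  de$flagged <- de$flagged | zero
  data.frame(subcluster = rownames(counts), lrt_stat = de$lrt_stat,
             p = de$p, q = de$q, flagged = de$flagged,
             stringsAsFactors = FALSE)
}

#' Call significantly changed subclusters
#'
#' A subcluster is called \code{up} when FC > 2 and q < 0.05, \code{down}
#' when FC < 0.5 and q < 0.05, and \code{excluded} (before either) when it
#' has fewer than 20 cells in either the male or the female samples;
#' everything else is \code{ns}.
#'
#' @param fc named fold changes (\code{\link{abundance_fold_change}}).
#' @param q named q-values (\code{\link{test_abundance}} \code{q} column,
#'   named by subcluster).
#' @param tab the \code{abundance_table} (for per-sex cell counts).
#' @param config a \code{\link{pipeline_config}}.
#' @return data.frame: subcluster, fc, q, cells_male, cells_female, call.
#' @export
call_significant <- function(fc, q, tab, config = pipeline_config()) {
  sub <- rownames(tab$counts)
  sex <- tab$replicate_meta$sex
  by_sex <- vapply(c("M", "F"), function(s) {
    rowSums(tab$counts[, sex == s, drop = FALSE])
  }, numeric(length(sub)))
  fc <- fc[sub]
  q <- q[sub]
  call <- rep("ns", length(sub))
  call[fc > config$abundance_fc_min & q < config$de_fdr] <- "up"
  call[fc < 1 / config$abundance_fc_min & q < config$de_fdr] <- "down"
  excluded <- apply(by_sex, 1L, min) < config$abundance_min_cells_per_sex
  call[excluded] <- "excluded"
  data.frame(subcluster = sub, fc = unname(fc), q = unname(q),
             cells_male = by_sex[, "M"], cells_female = by_sex[, "F"],
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}
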