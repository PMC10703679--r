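#' Score-per-million peak filter
#'
#' Peak-caller scores (-log10 q-values) are normalized to "score per
#' million" — each score divided by the summed score of its peak set,
#' times 1e6 — so peak confidence is comparable across cell groups with
#' different read depths. Peaks at or above the cutoff (protocol: 1.3)
#' are kept.
#'
#' @param peaks data.frame with columns chrom, start, end, score (and
#'   optionally summit).
#' @param cutoff score-per-million cutoff.
#' @return the filtered data.frame with an added \code{spm} column.
#' @export
score_per_million_filter <- function(peaks, cutoff = 1.3) {
  stopifnot("score" %in% names(peaks))
  total <- sum(peaks$score)
  if (total == 0) stop("all peak scores are zero; score per million undefined")
  peaks$spm <- 1e6 * peaks$score / total
  peaks[peaks$spm >= cutoff, , drop = FALSE]
}

#' Merge summit-centered peak windows
#'
#' Extends each peak summit by \code{pad} bp on either side
#' ([summit - pad, summit + pad), half-open) and merges overlapping
#' windows. A window never shrinks its input interval (already-wide
#' intervals are kept), which makes the operation idempotent: merging
#' merged output is a no-op. Peaks without a summit fall back to the
#' interval midpoint with a warning.
#'
#' @param peaks data.frame with chrom, start, end and optionally summit
#'   (absolute 0-based position).
#' @param pad half-window (protocol: 250 bp).
#' @return data.frame of merged intervals: chrom, start, end, summit.
#' @export
merge_summit_peaks <- function(peaks, pad = 250L) {
  if (!"summit" %in% names(peaks) || anyNA(peaks$summit)) {
    warning("peak(s) without summit; using interval midpoints")
    mid <- floor((peaks$start + peaks$end) / 2)
    if (!"summit" %in% names(peaks)) peaks$summit <- mid
    peaks$summit[is.na(peaks$summit)] <- mid[is.na(peaks$summit)]
  }
  win_start <- pmin(peaks$start, peaks$summit - pad)
  win_end <- pmax(peaks$end, peaks$summit + pad)
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = win_start + 1L, end = win_end)
  )
  merged <- GenomicRanges::reduce(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    summit = as.integer(floor((GenomicRanges::start(merged) - 1L +
                                 GenomicRanges::end(merged)) / 2)),
    stringsAsFactors = FALSE
  )
}

#' Binary cell-by-peak accessibility matrix
#'
#' A cell is accessible at a peak iff at least one of its fragments
#' overlaps the peak; entries are 0/1 regardless of fragment count.
#'
#' @param fragments data.frame with cell, chrom, start, end (0-based
#'   half-open).
#' @param peaks data.frame with chrom, start, end.
#' @return sparse binary matrix, peaks x cells (peaks named
#'   "chrom:start-end").
#' @export
count_peak_accessibility <- function(fragments, peaks) {
  peak_ids <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  cells <- sort(unique(fragments$cell))
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$start + 1L,
                                                fragments$end))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(fr, pk, ignore.strand = TRUE)
  i <- S4Vectors::subjectHits(hits)
  j <- match(fragments$cell[S4Vectors::queryHits(hits)], cells)
  keep <- !duplicated(cbind(i, j))
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1L,
                       dims = c(length(peak_ids), length(cells)),
                       dimnames = list(peak_ids, cells))
}

#' Filter differentially accessible peaks
#'
#' Keeps peaks differentially accessible across cell types (q below the
#' FDR) with accessibility TPM above \code{tpm_min} in the target (first-
#' ranked) cell type.
#'
#' @param de DE table from \code{\link{de_test_lrt}} on the peak matrix.
#' @param tpm cell types x peaks matrix (\code{\link{tpm_aggregate}}).
#' @param config a \code{\link{pipeline_config}} (de_fdr,
#'   atac_diff_tpm_min).
#' @return data.frame of kept peaks with target type and its TPM.
#' @export
differential_peak_filter <- function(de, tpm, config = pipeline_config()) {
  rk <- rank_fold_change(tpm, pseudocount = 0)
  m <- match(de$feature, rk$feature)
  if (anyNA(m)) stop("peak sets of DE table and TPM matrix differ")
  tab <- cbind(de, rk[m, c("first_group", "tpm_first")])
  keep <- !is.na(tab$q) & tab$q < config$de_fdr &
    tab$tpm_first > config$atac_diff_tpm_min
  rownames(tab) <- NULL
  tab[keep, , drop = FALSE]
}

#' Link peaks to genes by expression-accessibility correlation
#'
#' For every gene, correlates its expression with the accessibility of
#' peaks whose centers lie within \code{cre_window_bp} of the gene's TSS,
#' across subcluster pseudo-cells; both matrices must be TPM-normalized
#' and log-transformed on matched pseudo-cell columns, and only genes and
#' peaks with maximum TPM above \code{cre_tpm_min} enter. The null is
#' built by permuting the subcluster identity of the ATAC matrix
#' (\code{cre_n_perm} rounds pooled) and the PCC threshold is the smallest
#' observed value t with (permuted >= t)/(observed >= t) <= \code{cre_fdr},
#' estimated on the positive tail. Retained links are positive, pruned to
#' the best gene per peak, and distal peaks overlapping another gene's
#' promoter (TSS +/- \code{cre_promoter_bp}) are removed.
#'
#' @param rna genes x pseudo-cells log-TPM matrix.
#' @param rna_tpm genes x pseudo-cells TPM matrix (pre-log), for the
#'   retention filter.
#' @param atac peaks x pseudo-cells log-TPM accessibility matrix (rownames
#'   "chrom:start-end").
#' @param atac_tpm peaks x pseudo-cells TPM matrix (pre-log).
#' @param ann a \code{\link{genome_annotation}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param seed RNG seed for the permutation.
#' @return list: \code{links} (data.frame peak, gene, pcc, distance_to_tss),
#'   \code{threshold} (PCC cutoff), \code{candidates} (number of tested
#'   pairs), \code{skipped} (constant-vector pairs).
#' @export
link_peaks_to_genes <- function(rna, rna_tpm, atac, atac_tpm, ann,
                                config = pipeline_config(), seed = 1L) {
  stopifnot(identical(colnames(rna), colnames(atac)))
  genes_ok <- rownames(rna)[apply(rna_tpm, 1L, max) > config$cre_tpm_min]
  peaks_ok <- rownames(atac)[apply(atac_tpm, 1L, max) > config$cre_tpm_min]
  genes_ok <- intersect(genes_ok, ann$genes$gene_id)
  pk <- .parse_peak_ids(peaks_ok)
  pk$center <- floor((pk$start + pk$end) / 2)

  tss <- ann$tss[genes_ok]
  gchrom <- ann$genes$chrom[match(genes_ok, ann$genes$gene_id)]
  cand <- do.call(rbind, lapply(seq_along(genes_ok), function(gi) {
    sel <- pk$chrom == gchrom[gi] &
      abs(pk$center - tss[gi]) <= config$cre_window_bp
    if (!any(sel)) return(NULL)
    data.frame(gene = genes_ok[gi], peak = peaks_ok[sel],
               distance_to_tss = pk$center[sel] - tss[gi],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(list(links = data.frame(), threshold = NA_real_,
                candidates = 0L, skipped = 0L))
  }
  R <- as.matrix(rna[cand$gene, , drop = FALSE])
  A <- as.matrix(atac[cand$peak, , drop = FALSE])
  const <- apply(R, 1L, stats::sd) == 0 | apply(A, 1L, stats::sd) == 0
  skipped <- sum(const)
  cand <- cand[!const, , drop = FALSE]
  R <- R[!const, , drop = FALSE]
  A <- A[!const, , drop = FALSE]
  obs <- .rowwise_pcc(R, A)

  set.seed(seed)
  perm <- unlist(lapply(seq_len(config$cre_n_perm), function(r) {
    .rowwise_pcc(R, A[, sample(ncol(A)), drop = FALSE])
  }))

  thr <- .empirical_fdr_threshold(obs, perm, config$cre_fdr,
                                  n_perm = config$cre_n_perm)
  cand$pcc <- obs
  links <- cand[obs > 0 & obs >= thr, , drop = FALSE]
  if (nrow(links)) {
    # best gene per peak
    links <- links[order(links$peak, -links$pcc), , drop = FALSE]
    links <- links[!duplicated(links$peak), , drop = FALSE]
    links <- .prune_promoter_overlaps(links, ann, config)
    rownames(links) <- NULL
  }
  list(links = links, threshold = thr, candidates = length(obs),
       skipped = skipped)
}

.parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("peak id not 'chrom:start-end': ", ids[which(bad)[1L]])
  data.frame(id = ids,
             chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

.rowwise_pcc <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
}

# smallest observed positive value t with FDRhat(t) <= alpha, where
# FDRhat(t) = (#perm >= t / n_perm) / (#obs >= t)
.empirical_fdr_threshold <- function(obs, perm, alpha, n_perm = 1L) {
  cand <- sort(unique(obs[obs > 0]))
  perm_sorted <- sort(perm)
  obs_sorted <- sort(obs)
  n_ge <- function(sorted, t) length(sorted) - findInterval(t, sorted, left.open = TRUE)
  for (t in cand) {
    fdr <- (n_ge(perm_sorted, t) / n_perm) / n_ge(obs_sorted, t)
    if (fdr <= alpha) return(t)
  }
  Inf
}

.prune_promoter_overlaps <- function(links, ann, config) {
  pk <- .parse_peak_ids(links$peak)
  pad <- config$cre_promoter_bp
  prom_lo <- ann$tss - pad
  prom_hi <- ann$tss + pad
  gchrom <- ann$genes$chrom
  gid <- ann$genes$gene_id
  drop <- logical(nrow(links))
  for (i in seq_len(nrow(links))) {
    # distal = not in its own gene's promoter
    own <- match(links$gene[i], gid)
    in_own <- pk$chrom[i] == gchrom[own] &&
      pk$end[i] > prom_lo[own] && pk$start[i] < prom_hi[own]
    if (in_own) next
    other <- which(gchrom == pk$chrom[i] & gid != links$gene[i] &
                     prom_lo < pk$end[i] & prom_hi > pk$start[i])
    drop[i] <- length(other) > 0L
  }
  links[!drop, , drop = FALSE]
}

#' Correlate transcription-factor motif activity with TF expression
#'
#' The single-cell motif deviation matrix is min-max rescaled to (0, 10)
#' (one global monotone rescale, so cross-cell structure is preserved),
#' both matrices are aggregated (averaged) per cell-type label and
#' z-scaled across labels, and the Pearson correlation between each TF's
#' motif activity and its own expression across labels is returned. TFs
#' without a motif, or with a constant aggregated vector (PCC undefined),
#' are skipped and listed.
#'
#' @param deviations motifs x cells matrix of motif deviation scores.
#' @param expression genes x cells expression matrix (normalized).
#' @param labels cell-type label per cell (same cells, same order, both
#'   matrices).
#' @param tf_map data.frame with columns \code{tf} (gene) and \code{motif}.
#' @param config a \code{\link{pipeline_config}} (motif_rescale_range).
#' @return list: \code{pcc} (named per TF), \code{skipped} (TFs without a
#'   usable motif or with constant vectors).
#' @export
correlate_tf_activity <- function(deviations, expression, labels, tf_map,
                                  config = pipeline_config()) {
  stopifnot(ncol(deviations) == ncol(expression),
            ncol(deviations) == length(labels))
  rng <- config$motif_rescale_range
  dev <- as.matrix(deviations)
  if (max(dev) > min(dev)) {
    dev <- rng[1L] + (dev - min(dev)) / (max(dev) - min(dev)) *
      (rng[2L] - rng[1L])
  }
  agg <- function(m) {
    t(apply(m, 1L, function(v) tapply(v, labels, mean)))
  }
  dev_agg <- agg(dev)
  expr_agg <- agg(as.matrix(expression))
  zscale <- function(m) t(scale(t(m)))
  dev_z <- zscale(dev_agg)
  expr_z <- zscale(expr_agg)
  pcc <- stats::setNames(rep(NA_real_, nrow(tf_map)), tf_map$tf)
  skipped <- character()
  for (i in seq_len(nrow(tf_map))) {
    tf <- tf_map$tf[i]
    mo <- tf_map$motif[i]
    if (!mo %in% rownames(dev_z) || !tf %in% rownames(expr_z) ||
        anyNA(dev_z[mo, ]) || anyNA(expr_z[tf, ])) {
      skipped <- c(skipped, tf)
      next
    }
    pcc[tf] <- stats::cor(dev_z[mo, ], expr_z[tf, ])
  }
  list(pcc = pcc[!is.na(pcc)], skipped = skipped)
}
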