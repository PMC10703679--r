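#' Merge dT and randomN pseudo-cells into physical cells
#'
#' Reads primed by the short oligo-dT and the random-hexamer RT primers are
#' counted as independent pseudo-cells upstream; a physical cell is kept
#' only when both primer classes identified it, and its counts are the
#' element-wise sum of its two columns. Per-cell statistics are pooled, so
#' the unassigned fraction of a merged cell is
#' (ambiguous + discarded) / total over both primer columns.
#'
#' @param gene_cm,exon_cm gene- and exon-level \code{\link{count_matrix}}
#'   objects whose cells are named \code{"sample.rtwell.lig.primer"}.
#' @return list with merged \code{gene} and \code{exon} matrices (cells
#'   named \code{"sample.rtwell.lig"}), plus \code{dropped}: pseudo-cells
#'   lacking the other primer class.
#' @export
merge_primer_cells <- function(gene_cm, exon_cm) {
  stopifnot(identical(gene_cm$cells, exon_cm$cells))
  parts <- strsplit(gene_cm$cells, ".", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop("cell names must be sample.rtwell.lig.primer")
  primer <- vapply(parts, `[`, "", 4L)
  if (!all(primer %in% c("dT", "randomN"))) stop("unknown primer class in cell names")
  phys <- vapply(parts, function(p) paste(p[1:3], collapse = "."), "")
  tab <- table(phys, primer)
  if (any(tab > 1L)) stop("duplicate merged cell IDs (same physical cell and primer twice)")
  keep_ids <- rownames(tab)[tab[, "dT"] > 0 & tab[, "randomN"] > 0]
  dropped <- setdiff(unique(phys), keep_ids)
  keep <- phys %in% keep_ids

  merge_one <- function(cm) {
    counts <- .aggregate_columns(cm$counts[, keep, drop = FALSE], phys[keep])
    counts <- counts[, keep_ids, drop = FALSE]
    st <- cm$per_cell_stats
    if (!is.null(st)) {
      st <- st[keep, , drop = FALSE]
      num <- c("total_reads", "assigned", "ambiguous", "discarded", "duplicates")
      agg <- stats::aggregate(st[num], by = list(cell = phys[keep]), FUN = sum)
      agg <- agg[match(keep_ids, agg$cell), , drop = FALSE]
      st <- agg
    }
    count_matrix(counts, features = cm$features, cells = keep_ids,
                 per_cell_stats = st)
  }
  list(gene = merge_one(gene_cm), exon = merge_one(exon_cm), dropped = dropped)
}

#' Per-cell quality-control filter
#'
#' A cell fails when any of the three criteria hold, with the protocol's
#' strict inequalities: unassigned-read fraction > 30\%, UMIs > 20,000, or
#' detected genes < 200 (equality passes). Every violated criterion is
#' recorded, so a cell can fail for several reasons at once.
#'
#' @param cm merged gene-level \code{\link{count_matrix}} with
#'   per-cell statistics.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{matrix} (passing cells only) and \code{records}
#'   data.frame: cell_id, umis, genes_detected, unassigned_frac, pass,
#'   fail_reasons (comma-joined; empty iff pass).
#' @export
qc_filter <- function(cm, config = pipeline_config()) {
  if (is.null(cm$per_cell_stats)) stop("qc_filter requires per_cell_stats")
  umis <- Matrix::colSums(cm$counts)
  genes <- Matrix::colSums(cm$counts > 0)
  uf <- cm$per_cell_stats$unassigned_frac
  reasons <- mapply(function(u, g, f) {
    r <- character()
    if (f > config$qc_max_unassigned_frac) r <- c(r, "unassigned")
    if (u > config$qc_max_umis) r <- c(r, "umis")
    if (g < config$qc_min_genes) r <- c(r, "genes")
    paste(r, collapse = ",")
  }, umis, genes, uf)
  records <- data.frame(
    cell_id = cm$cells, umis = as.integer(umis),
    genes_detected = as.integer(genes), unassigned_frac = uf,
    pass = reasons == "", fail_reasons = reasons,
    stringsAsFactors = FALSE
  )
  keep <- which(records$pass)
  filtered <- count_matrix(cm$counts[, keep, drop = FALSE],
                           features = cm$features, cells = cm$cells[keep],
                           per_cell_stats = cm$per_cell_stats[keep, , drop = FALSE])
  list(matrix = filtered, records = records)
}

#' Remove cells flagged as doublets by an external scorer
#'
#' Doublet scores are computed outside this package (e.g. by a simulated-
#' doublet KNN scorer) and supplied per cell; cells strictly above the
#' threshold are removed.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param scores named numeric vector or two-column data.frame
#'   (cell_id, score) covering every cell.
#' @param threshold removal threshold; strict inequality.
#' @return list with \code{matrix} (kept cells) and \code{removed}
#'   (cell IDs removed as doublets).
#' @export
apply_doublet_scores <- function(cm, scores, threshold = 0.5) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores[[2L]], scores[[1L]])
  }
  missing <- setdiff(cm$cells, names(scores))
  if (length(missing)) {
    stop("no doublet score for cell(s): ",
         paste(missing[1:min(3, length(missing))], collapse = ", "))
  }
  s <- scores[cm$cells]
  keep <- which(s <= threshold)
  st <- if (is.null(cm$per_cell_stats)) NULL else cm$per_cell_stats[keep, , drop = FALSE]
  list(matrix = count_matrix(cm$counts[, keep, drop = FALSE],
                             features = cm$features, cells = cm$cells[keep],
                             per_cell_stats = st),
       removed = cm$cells[s > threshold])
}
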