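#' Sparse feature-by-cell UMI count matrix
#'
#' Container for gene- or exon-level UMI counts with the per-cell read
#' assignment statistics that QC needs. Features are rows and cells columns,
#' following the usual single-cell convention. Per-cell statistics must
#' satisfy the conservation identity
#' \code{assigned + ambiguous + discarded + duplicates = total_reads}, and
#' \code{unassigned_frac = (ambiguous + discarded) / total_reads}.
#'
#' @param counts matrix or sparse Matrix of non-negative integers,
#'   features x cells.
#' @param features character vector of feature IDs (rownames).
#' @param cells character vector of cell barcodes (colnames).
#' @param per_cell_stats data.frame with columns cell, total_reads, assigned,
#'   ambiguous, discarded, duplicates; \code{unassigned_frac} is derived.
#'   May be \code{NULL} for matrices that never saw reads (e.g. simulated).
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, features = rownames(counts),
                         cells = colnames(counts), per_cell_stats = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(features) || is.null(cells)) {
    stop("count_matrix requires feature and cell names")
  }
  if (length(features) != nrow(counts) || length(cells) != ncol(counts)) {
    stop("feature/cell name lengths do not match matrix dimensions")
  }
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  dimnames(counts) <- list(features, cells)
  if (!is.null(per_cell_stats)) {
    per_cell_stats <- .validate_cell_stats(per_cell_stats, cells)
  }
  structure(list(counts = counts, features = features, cells = cells,
                 per_cell_stats = per_cell_stats),
            class = "count_matrix")
}

.validate_cell_stats <- function(st, cells) {
  need <- c("cell", "total_reads", "assigned", "ambiguous", "discarded",
            "duplicates")
  stopifnot(all(need %in% names(st)))
  st <- as.data.frame(st)
  m <- match(cells, st$cell)
  if (anyNA(m)) stop("per_cell_stats missing cell(s): ",
                     paste(cells[is.na(m)][1:min(3, sum(is.na(m)))], collapse = ", "))
  st <- st[m, , drop = FALSE]
  rownames(st) <- NULL
  tot <- st$assigned + st$ambiguous + st$discarded + st$duplicates
  if (!isTRUE(all.equal(tot, st$total_reads))) {
    stop("per_cell_stats violate read conservation")
  }
  st$unassigned_frac <- ifelse(st$total_reads > 0,
                               (st$ambiguous + st$discarded) / st$total_reads, 0)
  st
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "features x", ncol(x$counts),
      "cells;", format(sum(x$counts), big.mark = ","), "UMIs\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix as a MatrixMarket bundle
#'
#' Writes \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv} and
#' (when present) \code{per_cell_stats.tsv} into \code{dir}. The round trip
#' through \code{read_count_matrix} reproduces the object exactly.
#'
#' @param cm a \code{count_matrix}.
#' @param dir directory (created if missing).
#' @return \code{write_count_matrix}: \code{dir}, invisibly.
#'   \code{read_count_matrix}: a \code{count_matrix}.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(cm$features, file.path(dir, "features.tsv"))
  writeLines(cm$cells, file.path(dir, "barcodes.tsv"))
  if (!is.null(cm$per_cell_stats)) {
    utils::write.table(cm$per_cell_stats, file.path(dir, "per_cell_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  features <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  stats_path <- file.path(dir, "per_cell_stats.tsv")
  st <- if (file.exists(stats_path)) {
    utils::read.table(stats_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  count_matrix(m, features, cells, per_cell_stats = st)
}

#' Library-size log normalization
#'
#' Scales each cell to its library size, multiplies by \code{scale}
#' (default 100,000) and applies \code{log1p}:
#' \code{x' = log(1 + scale * x / libsize)}. Cells with zero library size
#' cannot be normalized; they are excluded from the output and reported in
#' the \code{"excluded_cells"} attribute rather than silently zeroed.
#'
#' @param x a \code{count_matrix}, or a numeric matrix/sparse Matrix with
#'   features as rows and cells as columns, or a single vector (treated as
#'   one cell).
#' @param scale scale factor (the protocol uses 1e5).
#' @return A dense or sparse numeric matrix of normalized expression with an
#'   \code{"excluded_cells"} attribute naming dropped all-zero cells.
#' @examples
#' m <- matrix(c(10, 0, 0, 5), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' normalize_log(m)["g1", "c1"]  # log(1 + 1e5)
#' @export
normalize_log <- function(x, scale = 1e5) {
  if (inherits(x, "count_matrix")) x <- x$counts
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(names(x), "cell"))
  libsize <- Matrix::colSums(x)
  excluded <- colnames(x)[libsize == 0]
  keep <- libsize > 0
  x <- x[, keep, drop = FALSE]
  out <- log1p(x %*% Matrix::Diagonal(x = scale / libsize[keep]))
  dimnames(out) <- dimnames(x)
  attr(out, "excluded_cells") <- excluded
  out
}

#' Group-level counts-per-million aggregation
#'
#' Sums raw counts within each cell group and rescales each group to
#' counts-per-million; for UMI data no length normalization applies, so this
#' is the "TPM" used for marker cutoffs. Rows (groups) sum to 1e6.
#'
#' @param x a \code{count_matrix} or features x cells matrix.
#' @param labels cell grouping (one label per cell). Cells with \code{NA}
#'   labels are an error naming the offending cell.
#' @return groups x features dense matrix of counts-per-million. Groups with
#'   zero total counts are excluded.
#' @export
tpm_aggregate <- function(x, labels) {
  if (inherits(x, "count_matrix")) x <- x$counts
  if (length(labels) != ncol(x)) stop("one label per cell required")
  if (anyNA(labels)) {
    stop("cell(s) without a label: ",
         paste(colnames(x)[is.na(labels)][1:min(3, sum(is.na(labels)))],
               collapse = ", "))
  }
  labels <- as.character(labels)
  agg <- .aggregate_columns(x, labels)            # features x groups
  totals <- colSums(agg)
  agg <- agg[, totals > 0, drop = FALSE]
  totals <- totals[totals > 0]
  t(sweep(agg, 2L, totals, `/`) * 1e6)            # groups x features
}

# sum columns of a (sparse) matrix by group label -> features x groups dense
.aggregate_columns <- function(x, labels) {
  f <- factor(labels)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  out <- as.matrix(x %*% ind)
  colnames(out) <- levels(f)
  rownames(out) <- rownames(x)
  out
}
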