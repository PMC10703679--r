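#' Ingest aligned reads from SAM/BAM as fragments
#'
#' Reads primary alignments, groups records sharing a read name (mate
#' pairs) and unions their intervals into one fragment per template, so a
#' template is counted once. Fragment strand is the strand of the first
#' record encountered for the name (for the single cDNA read of this
#' chemistry there is one record per template). Mates on different
#' chromosomes keep only the first record. Coordinates are converted from
#' SAM's 1-based to the package's 0-based half-open convention.
#'
#' @param path SAM or BAM path. SAM files are converted internally.
#' @return data.frame: name, chrom, start, end, strand (0-based half-open).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) {
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    name = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$name)) {
    first <- !duplicated(df$name)
    # union mate intervals on the first mate's chromosome
    keep <- df[first, , drop = FALSE]
    idx <- split(seq_len(nrow(df)), match(df$name, keep$name))
    keep$start <- vapply(seq_along(idx), function(i) {
      j <- idx[[i]]
      j <- j[df$chrom[j] == keep$chrom[i]]
      min(df$start[j])
    }, 0L)
    keep$end <- vapply(seq_along(idx), function(i) {
      j <- idx[[i]]
      j <- j[df$chrom[j] == keep$chrom[i]]
      max(df$end[j])
    }, 0L)
    df <- keep
  }
  rownames(df) <- NULL
  df
}

#' Remove PCR duplicates by (cell, UMI, position) key
#'
#' Two fragments are PCR duplicates when they share cell barcode, UMI,
#' chromosome, fragment start and strand; one representative is kept. The
#' fragment start (not end) anchors the key because the 3' end varies with
#' trimming. UMIs are compared exactly.
#'
#' @param frags data.frame with columns cell, umi, chrom, start, strand
#'   (additional columns pass through).
#' @return list with \code{unique} (deduplicated data.frame) and
#'   \code{duplicates} (named per-cell duplicate counts, zero-filled for
#'   cells without duplicates).
#' @export
dedup_umis <- function(frags) {
  need <- c("cell", "umi", "chrom", "start", "strand")
  stopifnot(all(need %in% names(frags)))
  key <- paste(frags$cell, frags$umi, frags$chrom, frags$start, frags$strand,
               sep = "\r")
  dup <- duplicated(key)
  cells <- unique(frags$cell)
  dup_counts <- vapply(split(dup, factor(frags$cell, levels = cells)), sum, 0L)
  list(unique = frags[!dup, , drop = FALSE], duplicates = dup_counts)
}

#' Assign aligned fragments to genes
#'
#' Applies the 3'-aware priority rules of the protocol, per fragment:
#' \enumerate{
#'   \item Sense-strand gene overlap. A single overlapping gene gives
#'     \code{gene_unique}. Multiple overlaps: oligo-dT fragments go to the
#'     gene with the closest annotated 3' end
#'     (\code{gene_3prime_tiebreak}); random-hexamer fragments are
#'     \code{ambiguous} and not counted.
#'   \item No sense overlap: a same-strand gene whose 3' terminus lies
#'     within \code{upstream_rescue_bp} upstream of the fragment is an
#'     \code{upstream_rescue} (nearest 3' end wins among several).
#'   \item Otherwise a uniquely overlapping opposite-strand gene is an
#'     \code{antisense_rescue}; several antisense candidates are
#'     \code{ambiguous}.
#'   \item Fragments overlapping nothing are \code{discarded}.
#' }
#' The 3'-distance is |fragment midpoint - gene 3' end|; exact ties break
#' lexicographically by gene_id. Fragments on chromosomes absent from the
#' annotation are discarded and counted separately.
#'
#' @param frags data.frame with chrom, start, end, strand and
#'   \code{primer} ("dT"/"randomN").
#' @param ann a \code{\link{genome_annotation}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return data.frame with columns \code{category} and \code{gene_id}
#'   (NA unless a gene was assigned), one row per fragment, input order.
#' @export
assign_read_to_gene <- function(frags, ann, config = pipeline_config()) {
  n <- nrow(frags)
  category <- rep("discarded", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(category = category, gene_id = gene_id,
                      stringsAsFactors = FALSE))
  }
  known <- frags$chrom %in% unique(ann$genes$chrom)
  no_chrom <- !known
  category[no_chrom] <- "discarded_no_chrom"

  idx <- which(known)
  if (length(idx)) {
    fr_gr <- GenomicRanges::GRanges(
      seqnames = frags$chrom[idx],
      ranges = IRanges::IRanges(start = frags$start[idx] + 1L,
                                end = frags$end[idx]),
      strand = frags$strand[idx]
    )
    # strand-aware (sense) and strand-blind overlaps in one pass each
    sense_hits <- GenomicRanges::findOverlaps(fr_gr, ann$gene_gr,
                                              ignore.strand = FALSE)
    any_hits <- GenomicRanges::findOverlaps(fr_gr, ann$gene_gr,
                                            ignore.strand = TRUE)
    sense_by_read <- split(S4Vectors::subjectHits(sense_hits),
                           factor(S4Vectors::queryHits(sense_hits),
                                  levels = seq_along(idx)))
    any_by_read <- split(S4Vectors::subjectHits(any_hits),
                         factor(S4Vectors::queryHits(any_hits),
                                levels = seq_along(idx)))
    tpe <- ann$three_prime_end
    gids <- ann$genes$gene_id
    gstrand <- ann$genes$strand
    gchrom <- ann$genes$chrom
    for (k in seq_along(idx)) {
      i <- idx[k]
      sense <- sense_by_read[[k]]
      if (length(sense) == 1L) {
        category[i] <- "gene_unique"
        gene_id[i] <- gids[sense]
        next
      }
      if (length(sense) > 1L) {
        if (identical(frags$primer[i], "dT")) {
          pick <- .closest_three_prime(frags$start[i], frags$end[i],
                                       gids[sense], tpe[sense])
          category[i] <- "gene_3prime_tiebreak"
          gene_id[i] <- pick
        } else {
          category[i] <- "ambiguous"
        }
        next
      }
      # upstream rescue: same-strand gene 3' end within window upstream
      cand <- which(gchrom == frags$chrom[i] & gstrand == frags$strand[i])
      if (length(cand)) {
        g3 <- tpe[cand]
        if (frags$strand[i] == "+") {
          hit <- cand[g3 < frags$start[i] & g3 >= frags$start[i] - config$upstream_rescue_bp]
        } else {
          hit <- cand[g3 >= frags$end[i] & g3 < frags$end[i] + config$upstream_rescue_bp]
        }
        if (length(hit)) {
          pick <- .closest_three_prime(frags$start[i], frags$end[i],
                                       gids[hit], tpe[hit])
          category[i] <- "upstream_rescue"
          gene_id[i] <- pick
          next
        }
      }
      anti <- setdiff(any_by_read[[k]], sense)
      if (length(anti) == 1L) {
        category[i] <- "antisense_rescue"
        gene_id[i] <- gids[anti]
      } else if (length(anti) > 1L) {
        category[i] <- "ambiguous"
      }  # else stays "discarded"
    }
  }
  data.frame(category = category, gene_id = gene_id, stringsAsFactors = FALSE)
}

# nearest gene 3' end to the fragment midpoint; lexicographic tie-break
.closest_three_prime <- function(start, end, gene_ids, tpes) {
  mid <- (start + end) / 2
  d <- abs(mid - tpes)
  cand <- gene_ids[d == min(d)]
  sort(cand)[1L]
}

#' Assign a gene-assigned fragment to an exon of that gene
#'
#' A fragment overlapping exactly one exon of its gene takes that exon;
#' with several overlapping exons the one with the largest overlap wins and
#' exact ties give \code{NA} (ambiguous); intronic fragments give
#' \code{NA}. Gene-level counts are unaffected either way.
#'
#' @param frags data.frame with chrom, start, end (0-based half-open).
#' @param gene_id gene per fragment (non-NA rows are processed).
#' @param ann a \code{\link{genome_annotation}}.
#' @return character vector of exon IDs or NA, one per fragment.
#' @export
assign_read_to_exon <- function(frags, gene_id, ann) {
  out <- rep(NA_character_, nrow(frags))
  todo <- which(!is.na(gene_id))
  if (!length(todo)) return(out)
  if (!all(gene_id[todo] %in% ann$genes$gene_id)) {
    stop("gene_id not in annotation: ",
         paste(setdiff(gene_id[todo], ann$genes$gene_id), collapse = ", "))
  }
  ex <- ann$exons
  ex_by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  for (i in todo) {
    js <- ex_by_gene[[gene_id[i]]]
    if (is.null(js)) next
    ov <- pmin(frags$end[i], ex$end[js]) - pmax(frags$start[i], ex$start[js])
    ov[ex$chrom[js] != frags$chrom[i]] <- 0
    hit <- js[ov > 0]
    ov <- ov[ov > 0]
    if (length(hit) == 1L) {
      out[i] <- ex$exon_id[hit]
    } else if (length(hit) > 1L) {
      best <- ov == max(ov)
      if (sum(best) == 1L) out[i] <- ex$exon_id[hit[best]]
    }
  }
  out
}

#' Count genes and exons from demultiplexed alignments
#'
#' Full counting stage: ingest SAM/BAM whose read names carry
#' \code{cell|umi|read_id} (see \code{\link{demultiplex_pairs}}), collapse
#' PCR duplicates per cell, apply the gene- and exon-assignment rules, and
#' return one gene and one exon \code{\link{count_matrix}} whose columns
#' are (cell x primer-class) pseudo-cells. Per-cell statistics satisfy
#' assigned + ambiguous + discarded + duplicates = total fragments.
#'
#' @param sam SAM/BAM path, or a fragments data.frame as returned by
#'   \code{\link{read_alignments}}.
#' @param ann a \code{\link{genome_annotation}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{gene} and \code{exon} \code{count_matrix}
#'   objects and \code{assignments} (per deduplicated fragment).
#' @export
count_features <- function(sam, ann, config = pipeline_config()) {
  frags <- if (is.character(sam)) read_alignments(sam) else sam
  if (nrow(frags) == 0L) {
    empty <- count_matrix(Matrix::Matrix(0L, 0L, 0L, sparse = TRUE),
                          features = character(), cells = character())
    return(list(gene = empty, exon = empty,
                assignments = data.frame()))
  }
  meta <- parse_demux_names(frags$name)
  frags <- cbind(frags, meta)
  cells <- sort(unique(frags$cell))
  total <- table(factor(frags$cell, levels = cells))

  dd <- dedup_umis(frags)
  uni <- dd$unique
  asg <- assign_read_to_gene(uni, ann, config)
  uni$gene_id <- asg$gene_id
  uni$category <- asg$category
  uni$exon_id <- assign_read_to_exon(uni, uni$gene_id, ann)

  assigned_cat <- c("gene_unique", "gene_3prime_tiebreak", "upstream_rescue",
                    "antisense_rescue")
  is_asg <- uni$category %in% assigned_cat
  is_amb <- uni$category == "ambiguous"
  is_dis <- startsWith(uni$category, "discarded")

  cf <- factor(uni$cell, levels = cells)
  st <- data.frame(
    cell = cells,
    total_reads = as.integer(total),
    assigned = as.integer(tapply(is_asg, cf, sum, default = 0L)),
    ambiguous = as.integer(tapply(is_amb, cf, sum, default = 0L)),
    discarded = as.integer(tapply(is_dis, cf, sum, default = 0L)),
    duplicates = as.integer(dd$duplicates[cells]),
    stringsAsFactors = FALSE
  )
  st$discarded_no_chrom <- as.integer(
    tapply(uni$category == "discarded_no_chrom", cf, sum, default = 0L))

  gene_cm <- .build_matrix(uni$gene_id[is_asg], uni$cell[is_asg],
                           ann$genes$gene_id, cells, st)
  has_ex <- is_asg & !is.na(uni$exon_id)
  exon_cm <- .build_matrix(uni$exon_id[has_ex], uni$cell[has_ex],
                           ann$exons$exon_id, cells, st)
  list(gene = gene_cm, exon = exon_cm, assignments = uni)
}

.build_matrix <- function(feat, cell, all_feat, all_cells, stats) {
  i <- match(feat, all_feat)
  j <- match(cell, all_cells)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1L,
                            dims = c(length(all_feat), length(all_cells)))
  count_matrix(m, features = all_feat, cells = all_cells,
               per_cell_stats = stats)
}
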