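#' Strand-aware gene/exon annotation index
#'
#' Holds gene and exon intervals in 0-based half-open coordinates together
#' with each gene's transcription start site (TSS) and 3' terminus, the two
#' anchors the read-assignment rules need. GTF input (1-based, inclusive) is
#' converted on ingest so that a single coordinate convention is used
#' throughout the package.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand
#'   (0-based half-open).
#' @param exons data.frame with columns exon_id, gene_id, chrom, start, end,
#'   strand (0-based half-open).
#' @return An object of class \code{genome_annotation} with elements
#'   \code{genes}, \code{exons}, \code{tss}, \code{three_prime_end} (named
#'   per gene) and cached \code{GRanges} for overlap queries.
#' @examples
#' g <- data.frame(gene_id = "A", chrom = "chr1", start = 0, end = 100,
#'                 strand = "+")
#' e <- data.frame(exon_id = "A.e1", gene_id = "A", chrom = "chr1",
#'                 start = 0, end = 50, strand = "+")
#' ann <- genome_annotation(g, e)
#' ann$tss[["A"]]
#' @export
genome_annotation <- function(genes, exons) {
  need_g <- c("gene_id", "chrom", "start", "end", "strand")
  need_e <- c("exon_id", "gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need_g %in% names(genes)), all(need_e %in% names(exons)))
  genes <- as.data.frame(genes)[, need_g]
  exons <- as.data.frame(exons)[, need_e]
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (anyDuplicated(exons$exon_id)) stop("duplicate exon_id in annotation")
  if (any(genes$end <= genes$start)) stop("gene intervals must satisfy end > start")
  if (any(exons$end <= exons$start)) stop("exon intervals must satisfy end > start")
  if (!all(genes$strand %in% c("+", "-")) || !all(exons$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  m <- match(exons$gene_id, genes$gene_id)
  if (anyNA(m)) stop("exon refers to unknown gene: ",
                     paste(unique(exons$gene_id[is.na(m)]), collapse = ", "))
  contained <- exons$start >= genes$start[m] & exons$end <= genes$end[m] &
    exons$chrom == genes$chrom[m] & exons$strand == genes$strand[m]
  if (!all(contained)) {
    stop("exon(s) not contained in their gene: ",
         paste(exons$exon_id[!contained], collapse = ", "))
  }
  # TSS is the first transcribed base; the 3' end the last (both 0-based).
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  tpe <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  names(tss) <- names(tpe) <- genes$gene_id
  obj <- list(
    genes = genes, exons = exons,
    tss = tss, three_prime_end = tpe,
    gene_gr = .df_to_granges(genes, genes$gene_id),
    exon_gr = .df_to_granges(exons, exons$exon_id)
  )
  structure(obj, class = "genome_annotation")
}

# 0-based half-open data.frame -> GRanges (1-based inclusive)
.df_to_granges <- function(df, names) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
  names(gr) <- names
  gr
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>", nrow(x$genes), "genes,", nrow(x$exons),
      "exons on", length(unique(x$genes$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Import annotation from a GTF file
#'
#' Reads gene and exon records from a GTF (via \pkg{rtracklayer}) and builds
#' a \code{\link{genome_annotation}}. GTF coordinates are 1-based inclusive
#' and are shifted to the package's 0-based half-open convention. If the GTF
#' lacks explicit \code{gene} rows, gene extents are taken as the span of
#' each gene's exons.
#'
#' @param path GTF file path.
#' @return A \code{genome_annotation}.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"gene_id" %in% names(df)) stop("GTF lacks gene_id attributes")
  ex <- df[df$type == "exon", , drop = FALSE]
  gn <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gn) == 0L) {
    sp <- split(ex, ex$gene_id)
    gn <- do.call(rbind, lapply(sp, function(d) {
      data.frame(seqnames = d$seqnames[1L], start = min(d$start),
                 end = max(d$end), strand = d$strand[1L],
                 gene_id = d$gene_id[1L])
    }))
  }
  genes <- data.frame(
    gene_id = gn$gene_id, chrom = as.character(gn$seqnames),
    start = gn$start - 1L, end = gn$end, strand = as.character(gn$strand)
  )
  exon_id <- if ("exon_id" %in% names(ex) && !anyNA(ex$exon_id)) {
    ex$exon_id
  } else {
    paste0(ex$gene_id, ".e", stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along))
  }
  exons <- data.frame(
    exon_id = exon_id, gene_id = ex$gene_id, chrom = as.character(ex$seqnames),
    start = ex$start - 1L, end = ex$end, strand = as.character(ex$strand)
  )
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  exons <- exons[order(exons$chrom, exons$start, exons$exon_id), ]
  rownames(genes) <- rownames(exons) <- NULL
  genome_annotation(genes, exons)
}

#' Write an annotation to GTF
#'
#' Inverse of \code{\link{read_annotation_gtf}} for the fields this package
#' uses; internal 0-based half-open intervals become 1-based inclusive.
#'
#' @param ann a \code{genome_annotation}.
#' @param path output GTF path.
#' @export
write_annotation_gtf <- function(ann, path) {
  gtf_row <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tsciduet\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  }
  g <- ann$genes
  e <- ann$exons
  lines <- c(
    gtf_row(g$chrom, "gene", g$start, g$end, g$strand,
            sprintf('gene_id "%s";', g$gene_id)),
    gtf_row(e$chrom, "exon", e$start, e$end, e$strand,
            sprintf('gene_id "%s"; exon_id "%s";', e$gene_id, e$exon_id))
  )
  writeLines(lines, path)
  invisible(path)
}
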