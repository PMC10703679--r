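#' Barcode whitelists
#'
#' A whitelist is a set of fixed-length index sequences with per-entry
#' annotations (sample and well for RT indices, well for ligation indices).
#' The RT whitelist additionally encodes the reverse-transcription primer
#' class of each well: oligo-dT ("dT") or random hexamer ("randomN").
#'
#' @param entries character vector of equal-length sequences.
#' @param annotations data.frame with one row per entry (may be empty).
#' @param name whitelist name.
#' @return An object of class \code{barcode_whitelist}.
#' @export
barcode_whitelist <- function(entries, annotations = NULL, name = "whitelist") {
  entries <- as.character(entries)
  if (length(unique(nchar(entries))) != 1L) stop("whitelist entries must share one length")
  if (anyDuplicated(entries)) stop("whitelist entries must be unique")
  if (is.null(annotations)) annotations <- data.frame(row.names = seq_along(entries))
  if (nrow(annotations) != length(entries)) stop("one annotation row per entry required")
  structure(list(name = name, entries = entries, annotations = annotations,
                 width = nchar(entries[1L])),
            class = "barcode_whitelist")
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat("<barcode_whitelist>", x$name, ":", length(x$entries), "entries of width",
      x$width, "\n")
  invisible(x)
}

#' Read / write a whitelist TSV (sequence column first, annotations after)
#' @param path TSV path.
#' @param wl a \code{barcode_whitelist}.
#' @param name whitelist name for the returned object.
#' @export
read_whitelist <- function(path, name = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  barcode_whitelist(df[[1L]], df[, -1L, drop = FALSE], name = name)
}

#' @rdname read_whitelist
#' @export
write_whitelist <- function(wl, path) {
  df <- cbind(data.frame(sequence = wl$entries), wl$annotations)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Match an observed index against a whitelist with mismatch correction
#'
#' Returns the unique whitelist entry within Hamming distance
#' \code{max_mismatch} of the observed sequence. Observations equally close
#' to two entries are rejected as \code{ambiguous} rather than assigned;
#' observations with no entry within range are rejected as \code{no_match}.
#' Indices sit at fixed read positions, so Hamming (not edit) distance is
#' the right metric.
#'
#' @param observed observed sequence(s); vectorized.
#' @param wl a \code{barcode_whitelist}.
#' @param max_mismatch maximum tolerated mismatches (default 1: "edit
#'   distance < 2").
#' @return data.frame with columns \code{entry} (matched sequence or NA),
#'   \code{index} (whitelist position or NA), \code{distance}, and
#'   \code{reason} (\code{""}, \code{"no_match"} or \code{"ambiguous"}).
#' @examples
#' wl <- barcode_whitelist(c("AAAA", "TTTT"))
#' match_barcode("AAAT", wl, 1)$entry
#' @export
match_barcode <- function(observed, wl, max_mismatch = 1L) {
  observed <- as.character(observed)
  if (any(nchar(observed) != wl$width)) {
    stop("observed barcode length differs from whitelist width ", wl$width,
         " (malformed read structure)")
  }
  n <- length(observed)
  idx <- match(observed, wl$entries)
  dist <- ifelse(is.na(idx), NA_integer_, 0L)
  reason <- rep("", n)
  todo <- which(is.na(idx))
  if (length(todo) && max_mismatch > 0L) {
    obs_mat <- .seq_char_matrix(observed[todo], wl$width)
    wl_mat <- .seq_char_matrix(wl$entries, wl$width)
    for (k in seq_along(todo)) {
      d <- colSums(t(wl_mat) != obs_mat[k, ])
      best <- min(d)
      if (best > max_mismatch) {
        reason[todo[k]] <- "no_match"
      } else if (sum(d == best) > 1L) {
        reason[todo[k]] <- "ambiguous"
      } else {
        idx[todo[k]] <- which.min(d)
        dist[todo[k]] <- as.integer(best)
      }
    }
  } else if (length(todo)) {
    reason[todo] <- "no_match"
  }
  data.frame(entry = ifelse(is.na(idx), NA_character_, wl$entries[idx]),
             index = idx, distance = dist, reason = reason,
             stringsAsFactors = FALSE)
}

.seq_char_matrix <- function(x, width) {
  matrix(unlist(strsplit(x, ""), use.names = FALSE), ncol = width, byrow = TRUE)
}

#' Trim poly(A) tails and low-quality tails from cDNA
#'
#' Removes, from the 3' end of each read, first any run of bases with Phred
#' quality below \code{min_qual}, then a terminal poly(A) run of at least
#' \code{min_polya} bases in which at most one non-A base per ten is
#' tolerated. The read is never lengthened; an empty result is allowed.
#'
#' @param seq character vector of read sequences.
#' @param qual character vector of Phred+33 quality strings (same lengths).
#' @param min_qual minimum base quality kept at the tail (default 20).
#' @param min_polya minimum poly(A) run length to trim (default 10).
#' @return data.frame with columns \code{seq} and \code{qual}, trimmed.
#' @export
trim_tail <- function(seq, qual, min_qual = 20L, min_polya = 10L) {
  stopifnot(length(seq) == length(qual), all(nchar(seq) == nchar(qual)))
  out_seq <- character(length(seq))
  out_qual <- character(length(seq))
  for (i in seq_along(seq)) {
    s <- strsplit(seq[i], "")[[1L]]
    q <- utf8ToInt(qual[i]) - 33L
    n <- length(s)
    # 1) strip low-quality tail
    while (n > 0L && q[n] < min_qual) n <- n - 1L
    # 2) strip a terminal poly(A) run: longest suffix that begins with A,
    #    has length >= min_polya and at most floor(len/10) non-A bases
    best <- 0L
    non_a <- 0L
    for (len in seq_len(n)) {
      first <- s[n - len + 1L]
      if (first != "A") non_a <- non_a + 1L
      if (first == "A" && len >= min_polya && non_a <= len %/% 10L) best <- len
    }
    n <- n - best
    out_seq[i] <- paste(s[seq_len(n)], collapse = "")
    out_qual[i] <- if (n > 0L) substr(qual[i], 1L, n) else ""
  }
  data.frame(seq = out_seq, qual = out_qual, stringsAsFactors = FALSE)
}

#' Read layout for combinatorial barcodes
#'
#' Read 1 carries the barcodes: ligation index, UMI, RT index, at the
#' offsets given here (1-based, inclusive). Read 2 is cDNA. The PCR index
#' is file-level metadata (reads are already split by PCR well upstream).
#'
#' @param lig_width,umi_width,rt_width widths of the three read-1 segments,
#'   in order.
#' @return A named list with start/end offsets per segment.
#' @export
read_layout <- function(lig_width = 10L, umi_width = 8L, rt_width = 10L) {
  list(
    lig = c(1L, lig_width),
    umi = c(lig_width + 1L, lig_width + umi_width),
    rt = c(lig_width + umi_width + 1L, lig_width + umi_width + rt_width),
    min_r1 = lig_width + umi_width + rt_width
  )
}

#' Demultiplex a paired FASTQ batch
#'
#' Decodes the combinatorial cell barcode of every read pair: extracts the
#' ligation index, UMI and RT index from read 1 at the layout's offsets,
#' corrects each index against its whitelist tolerating
#' \code{config$max_barcode_mismatch} mismatches, trims poly(A)/low-quality
#' tails from the cDNA (read 2), and emits reads renamed
#' \code{"<sample>.<rt_well>.<lig>.<primer>|<umi>|<read id>"} so the cell
#' identity survives alignment. dT and randomN reads from one physical cell
#' deliberately get distinct cell strings; they are counted as independent
#' cells until the QC merge.
#'
#' @param r1,r2 FASTQ paths (read 1 = barcodes, read 2 = cDNA), or
#'   \code{ShortRead::ShortReadQ} objects.
#' @param rt_wl RT whitelist; annotations must contain columns
#'   \code{sample_id}, \code{well}, \code{primer} ("dT"/"randomN").
#' @param lig_wl ligation whitelist; annotations must contain \code{well}.
#' @param config a \code{\link{pipeline_config}}.
#' @param layout a \code{\link{read_layout}}.
#' @param pcr_id PCR-well identifier of this file pair (metadata only).
#' @param out optional path; when given, assigned trimmed cDNA reads are
#'   written there as FASTQ.
#' @return list with \code{reads} (data.frame: read_id, cell, sample_id,
#'   rt_well, primer, lig_well, umi, seq, qual, reason), \code{report}
#'   (counts per outcome; assigned + rejections = input pairs) and
#'   \code{pcr_id}.
#' @export
demultiplex_pairs <- function(r1, r2, rt_wl, lig_wl, config = pipeline_config(),
                              layout = read_layout(), pcr_id = "pcr1",
                              out = NULL) {
  fq1 <- if (is.character(r1)) ShortRead::readFastq(r1) else r1
  fq2 <- if (is.character(r2)) ShortRead::readFastq(r2) else r2
  if (length(fq1) != length(fq2)) stop("read 1 / read 2 pair counts differ")
  ids <- sub("\\s.*$", "", as.character(ShortRead::id(fq1)))
  s1 <- as.character(ShortRead::sread(fq1))
  s2 <- as.character(ShortRead::sread(fq2))
  q2 <- as.character(Biostrings::quality(Biostrings::quality(fq2)))
  n <- length(s1)
  reason <- rep("", n)

  truncated <- nchar(s1) < layout$min_r1
  reason[truncated] <- "truncated"
  ok <- !truncated

  lig_obs <- substr(s1, layout$lig[1L], layout$lig[2L])
  umi <- substr(s1, layout$umi[1L], layout$umi[2L])
  rt_obs <- substr(s1, layout$rt[1L], layout$rt[2L])

  lig_m <- rt_m <- NULL
  if (any(ok)) {
    lig_m <- match_barcode(lig_obs[ok], lig_wl, config$max_barcode_mismatch)
    rt_m <- match_barcode(rt_obs[ok], rt_wl, config$max_barcode_mismatch)
    r <- rep("", sum(ok))
    r[lig_m$reason != ""] <- paste0("lig_", lig_m$reason[lig_m$reason != ""])
    bad_rt <- rt_m$reason != "" & r == ""
    r[bad_rt] <- paste0("rt_", rt_m$reason[bad_rt])
    reason[ok] <- r
  }

  assigned <- reason == ""
  cell <- rep(NA_character_, n)
  sample_id <- rt_well <- primer <- lig_well <- rep(NA_character_, n)
  if (any(assigned)) {
    ok_idx <- which(ok)
    a_in_ok <- match(which(assigned), ok_idx)
    rt_ann <- rt_wl$annotations[rt_m$index[a_in_ok], , drop = FALSE]
    lig_ann <- lig_wl$annotations[lig_m$index[a_in_ok], , drop = FALSE]
    sample_id[assigned] <- rt_ann$sample_id
    rt_well[assigned] <- rt_ann$well
    primer[assigned] <- rt_ann$primer
    lig_well[assigned] <- lig_ann$well
    cell[assigned] <- paste(rt_ann$sample_id, rt_ann$well, lig_ann$well,
                            rt_ann$primer, sep = ".")
  }

  trimmed <- trim_tail(s2, q2)
  reads <- data.frame(
    read_id = ids, cell = cell, sample_id = sample_id, rt_well = rt_well,
    primer = primer, lig_well = lig_well, umi = umi,
    seq = trimmed$seq, qual = trimmed$qual, reason = reason,
    stringsAsFactors = FALSE
  )
  report <- as.data.frame(table(outcome = ifelse(reason == "", "assigned", reason)),
                          stringsAsFactors = FALSE)
  names(report) <- c("outcome", "reads")
  if (!is.null(out)) {
    keep <- assigned & nchar(reads$seq) > 0L
    .write_fastq(paste0(cell[keep], "|", umi[keep], "|", ids[keep]),
                 reads$seq[keep], reads$qual[keep], out)
  }
  list(reads = reads, report = report, pcr_id = pcr_id)
}

.write_fastq <- function(ids, seq, qual, path) {
  fq <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(seq),
    quality = Biostrings::BStringSet(qual),
    id = Biostrings::BStringSet(ids)
  )
  if (file.exists(path)) file.remove(path)
  ShortRead::writeFastq(fq, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Parse demultiplexed read names back into barcode fields
#' @param names character vector "cell|umi|read_id".
#' @return data.frame with cell, sample_id, rt_well, lig_well, primer, umi,
#'   read_id.
#' @export
parse_demux_names <- function(names) {
  parts <- strsplit(names, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed read name: ", names[which(bad)[1L]])
  cell <- vapply(parts, `[`, "", 1L)
  cf <- strsplit(cell, ".", fixed = TRUE)
  bad <- lengths(cf) != 4L
  if (any(bad)) stop("malformed cell barcode in read name: ", cell[which(bad)[1L]])
  data.frame(
    cell = cell,
    sample_id = vapply(cf, `[`, "", 1L),
    rt_well = vapply(cf, `[`, "", 2L),
    lig_well = vapply(cf, `[`, "", 3L),
    primer = vapply(cf, `[`, "", 4L),
    umi = vapply(parts, `[`, "", 2L),
    read_id = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}
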