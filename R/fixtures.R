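#' Specification of the synthetic fixture bundle
#'
#' Parameters for every generator in the fixture module: barcode layout
#' and error rates, toy genome geometry, and the structure planted into
#' count matrices (clusters, abundance effects, modules, peak-gene links,
#' age signal). Fixed seed implies byte-identical outputs.
#'
#' @param n_samples number of biological samples (RT-plate sources).
#' @param wells_per_sample RT wells per sample (each well exists in a dT
#'   and a randomN version).
#' @param n_lig,n_pcr ligation and PCR index counts.
#' @param n_cells number of physical cells.
#' @param reads_per_cell mean read pairs per (cell x primer class).
#' @param n_genes genes in the toy genome (>= 4 so the mandated overlap /
#'   opposite-strand / gap constructs exist).
#' @param n_exons_per_gene exons per gene.
#' @param fraction_randomN_reads fraction of reads primed by random
#'   hexamers.
#' @param err1_frac,err2_frac fractions of reads carrying exactly one /
#'   exactly two barcode errors.
#' @param dup_frac fraction of additional reads planted as exact PCR
#'   duplicates.
#' @param barcode_width index width; \code{min_barcode_dist} minimum
#'   pairwise Hamming distance within each whitelist (3 makes 1-mismatch
#'   correction unambiguous).
#' @param n_clusters planted cell clusters; the last two share gene-level
#'   means and differ only in exon usage.
#' @param nb_dispersion negative-binomial dispersion of count noise
#'   (variance = mu + dispersion * mu^2).
#' @param abundance_fold planted case/control fold change of cluster 1.
#' @param n_modules planted gene modules; \code{genes_per_module} members
#'   each.
#' @param n_links,n_decoy_peaks planted peak-gene links and uncorrelated
#'   decoy peaks.
#' @param ages_months ages of the simulated animals;
#'   \code{animals_per_age} each; \code{n_age_genes} genes with an
#'   ln(age) slope.
#' @param seed RNG seed.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_samples = 2L, wells_per_sample = 4L, n_lig = 8L,
                         n_pcr = 2L, n_cells = 60L, reads_per_cell = 40L,
                         n_genes = 10L, n_exons_per_gene = 3L,
                         fraction_randomN_reads = 0.4,
                         err1_frac = 0.05, err2_frac = 0.02, dup_frac = 0.1,
                         barcode_width = 10L, min_barcode_dist = 3L,
                         n_clusters = 4L, nb_dispersion = 0.2,
                         abundance_fold = 3, n_modules = 4L,
                         genes_per_module = 50L, n_links = 50L,
                         n_decoy_peaks = 5000L, ages_months = c(3, 6, 21),
                         animals_per_age = 4L, n_age_genes = 50L,
                         seed = 1L) {
  spec <- as.list(environment())
  fr <- c(spec$fraction_randomN_reads, spec$err1_frac, spec$err2_frac,
          spec$dup_frac)
  if (any(fr < 0) || any(fr > 1)) stop("fixture fractions must lie in [0,1]")
  if (spec$err1_frac + spec$err2_frac > 1) stop("error fractions exceed 1")
  structure(spec, class = "fixture_spec")
}

# ---- whitelists -----------------------------------------------------------

#' Synthesize a whitelist with guaranteed minimum pairwise distance
#' @param n entries; @param width sequence width; @param min_dist minimum
#'   pairwise Hamming distance; @param seed RNG seed.
#' @param annotations optional annotation data.frame (n rows).
#' @param name whitelist name.
#' @return a \code{\link{barcode_whitelist}}.
#' @export
make_whitelist <- function(n, width = 10L, min_dist = 3L, seed = 1L,
                           annotations = NULL, name = "synthetic") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  entries <- character(0)
  mat <- matrix(character(0), 0, width)
  tries <- 0L
  while (length(entries) < n) {
    cand <- sample(bases, width, replace = TRUE)
    ok <- nrow(mat) == 0L ||
      min(rowSums(mat != matrix(cand, nrow(mat), width, byrow = TRUE))) >= min_dist
    if (ok) {
      entries <- c(entries, paste(cand, collapse = ""))
      mat <- rbind(mat, cand)
    }
    tries <- tries + 1L
    if (tries > 1e5) stop("cannot synthesize ", n, " codes of width ", width,
                          " at distance ", min_dist)
  }
  barcode_whitelist(entries, annotations, name = name)
}

#' Generate the RT / ligation / PCR whitelists of a fixture
#' @param spec a \code{\link{fixture_spec}}.
#' @return list rt, lig, pcr of \code{barcode_whitelist}.
#' @export
make_fixture_whitelists <- function(spec) {
  n_rt <- spec$n_samples * spec$wells_per_sample * 2L
  rt_ann <- expand.grid(
    primer = c("dT", "randomN"),
    well = sprintf("W%02d", seq_len(spec$wells_per_sample)),
    sample_id = sprintf("S%d", seq_len(spec$n_samples)),
    stringsAsFactors = FALSE
  )[, c("sample_id", "well", "primer")]
  rt <- make_whitelist(n_rt, spec$barcode_width, spec$min_barcode_dist,
                       seed = spec$seed + 11L, annotations = rt_ann,
                       name = "rt")
  lig <- make_whitelist(spec$n_lig, spec$barcode_width, spec$min_barcode_dist,
                        seed = spec$seed + 12L,
                        annotations = data.frame(
                          well = sprintf("L%02d", seq_len(spec$n_lig))),
                        name = "lig")
  pcr <- make_whitelist(spec$n_pcr, spec$barcode_width, spec$min_barcode_dist,
                        seed = spec$seed + 13L,
                        annotations = data.frame(
                          well = sprintf("P%02d", seq_len(spec$n_pcr))),
                        name = "pcr")
  list(rt = rt, lig = lig, pcr = pcr)
}

# ---- genome fixture -------------------------------------------------------

#' Build the toy genome and annotation
#'
#' Deterministically lays out \code{n_genes} genes on one chromosome so
#' that, by construction, genes 1 and 2 overlap on the same strand (to
#' exercise the closest-3' tie-break), genes 3 and 4 overlap on opposite
#' strands (antisense assignment), and all other gaps exceed the
#' upstream-rescue window. Writes FASTA and GTF when paths are given.
#'
#' @param spec a \code{\link{fixture_spec}} (needs n_genes >= 4).
#' @param fasta,gtf optional output paths.
#' @param gene_width,gap gene length and intergenic gap (gap must exceed
#'   the 1,000 bp rescue window).
#' @return list: \code{annotation} (a \code{\link{genome_annotation}}),
#'   \code{genome} (named character of chromosome sequences), and the
#'   paths written.
#' @export
make_genome_fixture <- function(spec, fasta = NULL, gtf = NULL,
                                gene_width = 2000L, gap = 2000L) {
  if (spec$n_genes < 4L) {
    stop("the mandated overlap and antisense constructs need n_genes >= 4 (got ",
         spec$n_genes, ")")
  }
  set.seed(spec$seed + 21L)
  starts <- integer(spec$n_genes)
  strands <- character(spec$n_genes)
  starts[1L] <- 1000L; strands[1L] <- "+"
  starts[2L] <- starts[1L] + gene_width - 500L; strands[2L] <- "+"   # overlap 500
  starts[3L] <- starts[2L] + gene_width + gap; strands[3L] <- "+"
  starts[4L] <- starts[3L] + 1000L; strands[4L] <- "-"               # antisense overlap
  if (spec$n_genes > 4L) {
    for (i in 5:spec$n_genes) {
      starts[i] <- starts[i - 1L] + gene_width + gap
      strands[i] <- c("+", "-")[(i %% 2L) + 1L]
    }
  }
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(spec$n_genes)),
    chrom = "chr1", start = starts, end = starts + gene_width,
    strand = strands, stringsAsFactors = FALSE
  )
  k <- spec$n_exons_per_gene
  # evenly spaced exons; last exon flush with the gene end
  rel_starts <- floor(seq(0L, gene_width - 300L, length.out = k))
  exons <- do.call(rbind, lapply(seq_len(spec$n_genes), function(i) {
    data.frame(
      exon_id = sprintf("%s.e%d", genes$gene_id[i], seq_len(k)),
      gene_id = genes$gene_id[i], chrom = "chr1",
      start = genes$start[i] + rel_starts,
      end = genes$start[i] + rel_starts + 300L,
      strand = genes$strand[i], stringsAsFactors = FALSE
    )
  }))
  ann <- genome_annotation(genes, exons)
  glen <- max(genes$end) + 3000L
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                           collapse = ""))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)
  }
  if (!is.null(gtf)) write_annotation_gtf(ann, gtf)
  list(annotation = ann, genome = genome, fasta = fasta, gtf = gtf)
}

# ---- read fixture ---------------------------------------------------------

#' Generate barcoded paired FASTQ, a truth table and a truth-placed SAM
#'
#' Plants reads of every assignment category the counting rules produce
#' (unique, 3'-tie-break, randomN-ambiguous, upstream rescue, antisense
#' rescue, discarded, plus exact PCR duplicates), with configurable
#' fractions of exactly-one and exactly-two barcode errors. Two-error
#' barcodes are resampled until they sit at Hamming distance >= 2 from
#' every whitelist entry, so their planted outcome (rejection) is exact.
#' The SAM places each read at its true locus with the name
#' \code{cell|umi|read_id} that a correct demultiplexer would assign;
#' reads with two barcode errors are left out of the SAM, as they would
#' be rejected upstream.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param genome result of \code{\link{make_genome_fixture}}.
#' @param whitelists result of \code{\link{make_fixture_whitelists}}.
#' @param dir output directory for r1.fastq, r2.fastq, truth.tsv,
#'   reads.sam (created if missing); NULL keeps everything in memory.
#' @return list: \code{truth} data.frame, \code{paths} (r1, r2, sam,
#'   truth), \code{cells} (cell table).
#' @export
make_read_fixture <- function(spec, genome, whitelists, dir = NULL) {
  set.seed(spec$seed + 31L)
  ann <- genome$annotation
  wl <- whitelists
  rt_ann <- wl$rt$annotations

  # physical cells: unique (sample, well, lig) triples
  combos <- expand.grid(
    sample_id = sprintf("S%d", seq_len(spec$n_samples)),
    well = sprintf("W%02d", seq_len(spec$wells_per_sample)),
    lig = wl$lig$annotations$well, stringsAsFactors = FALSE
  )
  if (nrow(combos) < spec$n_cells) {
    stop("n_cells exceeds available barcode combinations (", nrow(combos), ")")
  }
  cells <- combos[sample(nrow(combos), spec$n_cells), , drop = FALSE]
  rownames(cells) <- NULL

  cats <- c(gene_unique = 0.55, gene_3prime_tiebreak = 0.08, ambiguous = 0.07,
            upstream_rescue = 0.08, antisense_rescue = 0.08, discarded = 0.10,
            discarded_no_chrom = 0.04)
  rlen <- 80L
  genes <- ann$genes
  iso <- which(seq_len(nrow(genes)) > 4L)        # isolated genes
  if (!length(iso)) stop("need n_genes > 4 for isolated-gene read scenarios")

  n_base <- spec$n_cells * spec$reads_per_cell
  reads <- vector("list", n_base)
  for (r in seq_len(n_base)) {
    ci <- ((r - 1L) %% spec$n_cells) + 1L
    primer <- if (stats::runif(1) < spec$fraction_randomN_reads) "randomN" else "dT"
    cat_r <- sample(names(cats), 1L, prob = cats)
    # categories that need a specific primer
    if (cat_r == "gene_3prime_tiebreak") primer <- "dT"
    if (cat_r == "ambiguous") primer <- "randomN"
    pos <- .plant_read_position(cat_r, primer, ann, iso, rlen)
    reads[[r]] <- data.frame(
      read_id = sprintf("r%06d", r),
      sample_id = cells$sample_id[ci], rt_well = cells$well[ci],
      lig_well = cells$lig[ci], primer = primer,
      umi = paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
                  collapse = ""),
      category = pos$category, gene_id = pos$gene_id, exon_id = pos$exon_id,
      chrom = pos$chrom, start = pos$start, end = pos$end,
      strand = pos$strand, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, reads)
  truth$cell <- paste(truth$sample_id, truth$rt_well, truth$lig_well,
                      truth$primer, sep = ".")

  # planted exact duplicates: same cell, UMI, position
  n_dup <- round(spec$dup_frac * nrow(truth))
  if (n_dup > 0L) {
    src <- truth[sample(nrow(truth), n_dup, replace = FALSE), , drop = FALSE]
    src$read_id <- sprintf("d%06d", seq_len(n_dup))
    src$category <- "duplicate"
    truth <- rbind(truth, src)
  }
  truth$barcode_errors <- 0L
  n <- nrow(truth)
  err <- sample(c(1L, 2L, 0L), n, replace = TRUE,
                prob = c(spec$err1_frac, spec$err2_frac,
                         1 - spec$err1_frac - spec$err2_frac))
  truth$barcode_errors <- err

  # encode read 1: lig + umi + rt, with planted index errors
  rt_key <- paste(rt_ann$sample_id, rt_ann$well, rt_ann$primer)
  rt_idx <- match(paste(truth$sample_id, truth$rt_well, truth$primer), rt_key)
  lig_idx <- match(truth$lig_well, wl$lig$annotations$well)
  rt_seq <- wl$rt$entries[rt_idx]
  lig_seq <- wl$lig$entries[lig_idx]
  for (i in which(err > 0L)) {
    target <- sample(c("rt", "lig"), 1L)
    if (target == "rt") {
      rt_seq[i] <- .mutate_barcode(rt_seq[i], err[i], wl$rt$entries)
    } else {
      lig_seq[i] <- .mutate_barcode(lig_seq[i], err[i], wl$lig$entries)
    }
  }
  r1 <- paste0(lig_seq, truth$umi, rt_seq)
  r2 <- vapply(seq_len(n), function(i) {
    if (truth$chrom[i] %in% names(genome$genome)) {
      substr(genome$genome[[truth$chrom[i]]], truth$start[i] + 1L, truth$end[i])
    } else {
      paste(sample(c("A", "C", "G", "T"), rlen, replace = TRUE), collapse = "")
    }
  }, "")

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(r1 = file.path(dir, "r1.fastq"),
                  r2 = file.path(dir, "r2.fastq"),
                  sam = file.path(dir, "reads.sam"),
                  truth = file.path(dir, "truth.tsv"))
    .write_fastq(truth$read_id, r1, strrep("I", nchar(r1)), paths$r1)
    .write_fastq(truth$read_id, r2, strrep("I", nchar(r2)), paths$r2)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .write_fixture_sam(truth, genome, paths$sam)
  }
  list(truth = truth, paths = paths, cells = cells, r1 = r1, r2 = r2)
}

# a position realizing the requested assignment category
.plant_read_position <- function(category, primer, ann, iso, rlen) {
  genes <- ann$genes
  out <- list(category = category, gene_id = NA_character_,
              exon_id = NA_character_, chrom = "chr1")
  if (category == "gene_unique") {
    gi <- sample(iso, 1L)
    # half the reads inside a random exon, half intronic if introns exist
    ex <- ann$exons[ann$exons$gene_id == genes$gene_id[gi], , drop = FALSE]
    if (stats::runif(1) < 0.6) {
      e <- ex[sample(nrow(ex), 1L), , drop = FALSE]
      s <- e$start + sample.int(e$end - e$start - rlen, 1L)
      out$exon_id <- e$exon_id
    } else {
      s <- .intronic_start(genes[gi, ], ex, rlen)
      if (is.na(s)) {   # no intron wide enough; fall back to exon 1
        e <- ex[1L, , drop = FALSE]
        s <- e$start + sample.int(e$end - e$start - rlen, 1L)
        out$exon_id <- e$exon_id
      }
    }
    out$gene_id <- genes$gene_id[gi]
    out$start <- s; out$end <- s + rlen; out$strand <- genes$strand[gi]
  } else if (category %in% c("gene_3prime_tiebreak", "ambiguous")) {
    ov_lo <- max(genes$start[1:2])
    ov_hi <- min(genes$end[1:2])
    s <- ov_lo + sample.int(ov_hi - ov_lo - rlen, 1L)
    out$start <- s; out$end <- s + rlen; out$strand <- "+"
    if (category == "gene_3prime_tiebreak") {
      mid <- s + rlen / 2
      d <- abs(mid - ann$three_prime_end[genes$gene_id[1:2]])
      win <- genes$gene_id[1:2][d == min(d)]
      out$gene_id <- sort(win)[1L]
      out$exon_id <- .containing_exon(ann, out$gene_id, s, s + rlen)
    }
  } else if (category == "upstream_rescue") {
    cand <- iso[genes$strand[iso] == "+"]
    gi <- if (length(cand)) sample(cand, 1L) else iso[1L]
    if (genes$strand[gi] == "+") {
      s <- genes$end[gi] + sample.int(1000L - rlen - 10L, 1L)
      out$strand <- "+"
    } else {
      s <- genes$start[gi] - rlen - sample.int(1000L - rlen - 10L, 1L)
      out$strand <- "-"
    }
    out$gene_id <- genes$gene_id[gi]
    out$start <- s; out$end <- s + rlen
  } else if (category == "antisense_rescue") {
    gi <- sample(iso, 1L)
    ex <- ann$exons[ann$exons$gene_id == genes$gene_id[gi], , drop = FALSE]
    e <- ex[sample(nrow(ex), 1L), , drop = FALSE]
    s <- e$start + sample.int(e$end - e$start - rlen, 1L)
    out$gene_id <- genes$gene_id[gi]
    out$exon_id <- e$exon_id
    out$start <- s; out$end <- s + rlen
    out$strand <- if (genes$strand[gi] == "+") "-" else "+"
  } else if (category == "discarded") {
    # beyond the last gene, outside every rescue window
    s <- max(genes$end) + 1200L + sample.int(500L, 1L)
    out$start <- s; out$end <- s + rlen
    out$strand <- sample(c("+", "-"), 1L)
  } else {  # discarded_no_chrom
    out$chrom <- "chrU"
    s <- sample.int(1000L, 1L)
    out$start <- s; out$end <- s + rlen
    out$strand <- "+"
  }
  out
}

.intronic_start <- function(gene, exons, rlen) {
  exons <- exons[order(exons$start), , drop = FALSE]
  for (i in seq_len(nrow(exons) - 1L)) {
    lo <- exons$end[i]
    hi <- exons$start[i + 1L]
    if (hi - lo > rlen + 2L) return(lo + sample.int(hi - lo - rlen, 1L))
  }
  NA_integer_
}

.containing_exon <- function(ann, gene_id, start, end) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  ov <- pmin(end, ex$end) - pmax(start, ex$start)
  hit <- which(ov > 0)
  if (length(hit) == 1L) return(ex$exon_id[hit])
  if (length(hit) > 1L) {
    best <- hit[ov[hit] == max(ov[hit])]
    if (length(best) == 1L) return(ex$exon_id[best])
  }
  NA_character_
}

# mutate exactly n_err positions; two-error results are kept at distance
# >= 2 from every whitelist entry so their planted rejection is certain
.mutate_barcode <- function(seq, n_err, entries) {
  bases <- c("A", "C", "G", "T")
  repeat {
    s <- strsplit(seq, "")[[1L]]
    pos <- sample(length(s), n_err)
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    mut <- paste(s, collapse = "")
    if (n_err == 1L) return(mut)
    d <- vapply(entries, function(e) {
      sum(strsplit(e, "")[[1L]] != s)
    }, 0L)
    if (min(d) >= 2L) return(mut)
  }
}

.write_fixture_sam <- function(truth, genome, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$genome),
            nchar(genome$genome)),
    "@SQ\tSN:chrU\tLN:5000"
  )
  keep <- truth$barcode_errors < 2L      # two-error reads die at demux
  t2 <- truth[keep, , drop = FALSE]
  seq <- vapply(seq_len(nrow(t2)), function(i) {
    if (t2$chrom[i] %in% names(genome$genome)) {
      substr(genome$genome[[t2$chrom[i]]], t2$start[i] + 1L, t2$end[i])
    } else {
      strrep("N", t2$end[i] - t2$start[i])
    }
  }, "")
  flag <- ifelse(t2$strand == "-", 16L, 0L)
  recs <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  paste0(t2$cell, "|", t2$umi, "|", t2$read_id),
                  flag, t2$chrom, t2$start + 1L, t2$end - t2$start,
                  seq, strrep("I", nchar(seq)))
  writeLines(c(header, recs), path)
  invisible(path)
}

# ---- matrix fixtures ------------------------------------------------------

# NB counts with mean mu and dispersion phi (variance mu + phi mu^2)
.rnb <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate clustered gene and exon count matrices
#'
#' Plants \code{n_clusters} cell clusters. Gene-level means differ
#' between clusters except for the last two, which share gene means
#' exactly and differ only in exon usage: gene counts are split across
#' each gene's exons by per-cluster usage weights, so total gene
#' expression is identical while the exon matrix separates them. This is
#' the construction behind the exon-aware subclustering claim.
#'
#' @param n_cells cells; @param n_genes genes;
#'   @param n_exons_per_gene exons per gene; @param n_clusters clusters
#'   (>= 2; exon twins need >= 3); @param nb_dispersion NB dispersion
#'   (0 gives Poisson; negative planted as exact noiseless copies);
#'   @param mean_expr mean counts of an active gene;
#'   @param exon_twins plant the exon-usage twin pair (set FALSE for
#'   fixtures that need every cluster distinct at the gene level, e.g.
#'   deconvolution signatures); @param seed RNG seed.
#' @param cluster_sizes optional explicit sizes (must sum to n_cells).
#' @return list: \code{gene} and \code{exon} \code{\link{count_matrix}}
#'   objects (no read stats), \code{clusters} (truth labels),
#'   \code{gene_means} (genes x clusters), \code{exon_usage}.
#' @export
simulate_cluster_counts <- function(n_cells = 300L, n_genes = 100L,
                                    n_exons_per_gene = 3L, n_clusters = 4L,
                                    nb_dispersion = 0.2, mean_expr = 20,
                                    exon_twins = TRUE, seed = 1L,
                                    cluster_sizes = NULL) {
  set.seed(seed)
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(n_cells %/% n_clusters, n_clusters)
    cluster_sizes[1L] <- cluster_sizes[1L] + n_cells - sum(cluster_sizes)
  }
  stopifnot(sum(cluster_sizes) == n_cells, length(cluster_sizes) == n_clusters)
  labels <- rep(seq_len(n_clusters), cluster_sizes)

  # distinct gene programs; twins (last two clusters) share program
  twins <- isTRUE(exon_twins) && n_clusters >= 3L
  n_prog <- if (twins) n_clusters - 1L else n_clusters
  prog_of <- c(seq_len(n_prog), if (twins) n_prog)
  gene_means <- matrix(1, n_genes, n_prog)     # low baseline
  block <- max(5L, n_genes %/% (2L * n_prog))
  for (p in seq_len(n_prog)) {
    hi <- ((p - 1L) * block + 1L):min(p * block, n_genes)
    gene_means[hi, p] <- mean_expr
  }
  gene_means <- gene_means[, prog_of, drop = FALSE]   # genes x clusters

  # exon usage: uniform everywhere except the twin pair, which load
  # different exons of the last program's genes
  k <- n_exons_per_gene
  usage <- array(1 / k, dim = c(n_genes, k, n_clusters))
  if (twins) {
    twin_genes <- ((n_prog - 1L) * block + 1L):min(n_prog * block, n_genes)
    u1 <- c(0.9, rep(0.1 / (k - 1L), k - 1L))
    u2 <- c(rep(0.1 / (k - 1L), k - 1L), 0.9)
    for (g in twin_genes) {
      usage[g, , n_clusters - 1L] <- u1
      usage[g, , n_clusters] <- u2
    }
  }

  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  exon_ids <- as.vector(t(outer(gene_ids, seq_len(k),
                                function(g, e) sprintf("%s.e%d", g, e))))
  gene_counts <- matrix(0L, n_genes, n_cells)
  exon_counts <- matrix(0L, n_genes * k, n_cells)
  for (j in seq_len(n_cells)) {
    cl <- labels[j]
    mu <- gene_means[, cl]
    cnt <- if (nb_dispersion < 0) round(mu) else .rnb(n_genes, mu, nb_dispersion)
    gene_counts[, j] <- cnt
    for (g in which(cnt > 0L)) {
      ex <- if (nb_dispersion < 0) {
        round(cnt[g] * usage[g, , cl])
      } else {
        stats::rmultinom(1L, cnt[g], usage[g, , cl])[, 1L]
      }
      exon_counts[((g - 1L) * k + 1L):(g * k), j] <- ex
    }
  }
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  dimnames(gene_means) <- list(gene_ids, as.character(seq_len(n_clusters)))
  list(
    gene = count_matrix(gene_counts, gene_ids, cell_ids),
    exon = count_matrix(exon_counts, exon_ids, cell_ids),
    clusters = stats::setNames(labels, cell_ids),
    gene_means = gene_means,
    exon_usage = usage
  )
}

#' Simulate replicate-level abundance data
#'
#' Cell metadata for the differential-abundance test: RT wells (the
#' replicates) nested in animals, two conditions, both sexes, with
#' per-subcluster baseline proportions and planted case/control fold
#' changes on selected subclusters.
#'
#' @param n_subclusters subclusters; @param reps_per_condition RT wells
#'   per condition; @param cells_per_rep cells per well;
#'   @param fold_changes named numeric (subcluster index -> planted
#'   case/control fold change on the proportion scale); @param seed seed.
#' @return data.frame of cells: subcluster, well, animal, condition, sex.
#' @export
simulate_abundance_cells <- function(n_subclusters = 20L,
                                     reps_per_condition = 4L,
                                     cells_per_rep = 500L,
                                     fold_changes = NULL, seed = 1L) {
  set.seed(seed)
  base <- rep(1 / n_subclusters, n_subclusters)
  out <- list()
  for (cond in c("control", "case")) {
    p <- base
    if (!is.null(fold_changes) && cond == "case") {
      idx <- as.integer(names(fold_changes))
      p[idx] <- p[idx] * fold_changes
      p <- p / sum(p)
    }
    for (r in seq_len(reps_per_condition)) {
      well <- sprintf("%s_w%d", cond, r)
      a_idx <- ((r - 1L) %/% 2L) + 1L
      animal <- sprintf("%s_a%d", cond, a_idx)
      sex <- c("M", "F")[(a_idx - 1L) %% 2L + 1L]
      sub <- sample.int(n_subclusters, cells_per_rep, replace = TRUE, prob = p)
      out[[well]] <- data.frame(
        subcluster = sprintf("sc%02d", sub), well = well, animal = animal,
        condition = cond, sex = sex, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate spot profiles as mixtures of cell-type signatures
#'
#' Spatial spots are non-negative combinations of the signature columns
#' (on the normalized scale NNLS operates on), with Dirichlet weights
#' recorded as truth and optional multiplicative noise.
#'
#' @param signatures features x cell-types matrix (e.g. from
#'   \code{\link{build_signature_matrix}}).
#' @param n_spots spots; @param noise_sd multiplicative log-normal noise
#'   sd (0 = noiseless); @param seed seed.
#' @return list: \code{spots} (features x spots, signature scale),
#'   \code{weights} (spots x cell-types truth, rows sum to 1).
#' @export
simulate_spot_mixtures <- function(signatures, n_spots = 50L, noise_sd = 0,
                                   seed = 1L) {
  set.seed(seed)
  signatures <- as.matrix(signatures)
  k <- ncol(signatures)
  w <- matrix(stats::rgamma(n_spots * k, shape = 1), n_spots, k)
  w <- w / rowSums(w)
  spots <- signatures %*% t(w)
  if (noise_sd > 0) {
    spots <- spots * matrix(exp(stats::rnorm(length(spots), 0, noise_sd)),
                            nrow(spots))
  }
  dimnames(spots) <- list(rownames(signatures),
                          sprintf("spot%03d", seq_len(n_spots)))
  colnames(w) <- colnames(signatures)
  rownames(w) <- colnames(spots)
  list(spots = spots, weights = w)
}

#' Simulate a pseudobulk matrix with planted gene modules
#'
#' Each module has an archetype profile over subclusters (high in a
#' random subset, near zero elsewhere); member genes are scaled copies of
#' their archetype with multiplicative noise, which keeps the within-
#' module correlation structure that the cosine UMAP embedding groups.
#'
#' @param n_modules modules; @param genes_per_module members;
#'   @param n_subclusters pseudobulk columns; @param noise_sd log-normal
#'   noise; @param seed seed.
#' @return list: \code{pseudobulk} (genes x subclusters, count scale),
#'   \code{modules} (truth labels per gene).
#' @export
simulate_module_matrix <- function(n_modules = 4L, genes_per_module = 50L,
                                   n_subclusters = 24L, noise_sd = 0.8,
                                   seed = 1L) {
  set.seed(seed)
  arch <- matrix(0.05, n_modules, n_subclusters)
  on <- max(3L, n_subclusters %/% n_modules)
  cols <- sample(n_subclusters)
  for (m in seq_len(n_modules)) {
    idx <- cols[(((m - 1L) * on) %% n_subclusters) + seq_len(on)]
    idx <- idx[!is.na(idx) & idx <= n_subclusters]
    arch[m, idx] <- 50
  }
  genes <- n_modules * genes_per_module
  pb <- matrix(0, genes, n_subclusters)
  modules <- rep(seq_len(n_modules), each = genes_per_module)
  for (g in seq_len(genes)) {
    scale_g <- stats::runif(1, 0.5, 2)
    noise <- exp(stats::rnorm(n_subclusters, 0, noise_sd))
    pb[g, ] <- arch[modules[g], ] * scale_g * noise
  }
  dimnames(pb) <- list(sprintf("mg%03d", seq_len(genes)),
                       sprintf("sc%02d", seq_len(n_subclusters)))
  list(pseudobulk = pb, modules = stats::setNames(modules, rownames(pb)))
}

#' Simulate pseudo-cell RNA/ATAC matrices with planted peak-gene links
#'
#' Genes are laid out on a long chromosome; every peak sits within the
#' linkage window of its anchor gene's TSS. For planted links, peak
#' accessibility tracks the gene's expression across pseudo-cells (plus
#' noise); decoy peaks are independent of every gene. The realized
#' expression-accessibility PCC of each planted link is recorded so
#' recall can be conditioned on link strength.
#'
#' @param n_genes genes; @param n_links planted links;
#'   @param n_decoys decoy peaks; @param n_pseudocells pseudo-cell
#'   columns; @param link_noise_sd additive noise on linked peaks (on the
#'   log scale; smaller = stronger links); @param seed seed.
#' @return list: \code{rna}, \code{rna_tpm}, \code{atac},
#'   \code{atac_tpm} (matrices as \code{\link{link_peaks_to_genes}}
#'   expects), \code{annotation}, \code{links_truth} (gene, peak,
#'   true_pcc).
#' @export
simulate_linked_pseudocells <- function(n_genes = 200L, n_links = 50L,
                                        n_pseudocells = 30L,
                                        n_decoys = 5000L,
                                        link_noise_sd = 0.15, seed = 1L) {
  set.seed(seed)
  stopifnot(n_links <= n_genes)
  gene_ids <- sprintf("lg%04d", seq_len(n_genes))
  spacing <- 2e6
  genes <- data.frame(
    gene_id = gene_ids, chrom = "chr1",
    start = spacing * (seq_len(n_genes) - 1L) + 1e6,
    end = spacing * (seq_len(n_genes) - 1L) + 1e6 + 2000, strand = "+",
    stringsAsFactors = FALSE
  )
  exons <- data.frame(exon_id = paste0(gene_ids, ".e1"), gene_id = gene_ids,
                      chrom = "chr1", start = genes$start,
                      end = genes$end, strand = "+",
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, exons)

  # log-scale expression profiles across pseudo-cells
  expr_log <- matrix(stats::rnorm(n_genes * n_pseudocells, 4, 1.5),
                     n_genes, n_pseudocells,
                     dimnames = list(gene_ids, sprintf("pc%02d",
                                                       seq_len(n_pseudocells))))
  linked_genes <- sample(n_genes, n_links)
  n_peaks <- n_links + n_decoys
  anchor <- c(linked_genes, sample(n_genes, n_decoys, replace = TRUE))
  offset <- sample(seq(-4e5, 4e5, by = 500L), n_peaks, replace = TRUE)
  center <- ann$tss[anchor] + offset
  peak_ids <- sprintf("chr1:%d-%d", center - 250L, center + 250L)
  dup <- duplicated(peak_ids)
  while (any(dup)) {
    center[dup] <- center[dup] + 17L
    peak_ids <- sprintf("chr1:%d-%d", center - 250L, center + 250L)
    dup <- duplicated(peak_ids)
  }
  atac_log <- matrix(stats::rnorm(n_peaks * n_pseudocells, 4, 1.5),
                     n_peaks, n_pseudocells,
                     dimnames = list(peak_ids, colnames(expr_log)))
  for (l in seq_len(n_links)) {
    g <- linked_genes[l]
    atac_log[l, ] <- expr_log[g, ] +
      stats::rnorm(n_pseudocells, 0, link_noise_sd)
  }
  to_tpm <- function(m) {
    x <- exp(m)
    sweep(x, 2L, colSums(x), `/`) * 1e6
  }
  rna_tpm <- to_tpm(expr_log)
  atac_tpm <- to_tpm(atac_log)
  truth <- data.frame(
    gene = gene_ids[linked_genes], peak = peak_ids[seq_len(n_links)],
    true_pcc = vapply(seq_len(n_links), function(l) {
      stats::cor(log1p(rna_tpm[gene_ids[linked_genes[l]], ]),
                 log1p(atac_tpm[peak_ids[l], ]))
    }, 0), stringsAsFactors = FALSE
  )
  list(rna = log1p(rna_tpm), rna_tpm = rna_tpm,
       atac = log1p(atac_tpm), atac_tpm = atac_tpm,
       annotation = ann, links_truth = truth)
}

#' Simulate per-cell profiles with an ln(age) signal
#'
#' Animals at the given ages contribute cells whose normalized expression
#' is linear in ln(age) on the slope genes, plus optional Gaussian noise.
#' "Accelerated" animals carry the expression of
#' \code{acceleration_factor} times their age while keeping their
#' chronological label.
#'
#' @param n_genes genes; @param n_slope_genes genes with nonzero slope;
#'   @param ages_months ages; @param animals_per_age animals at each age;
#'   @param cells_per_animal cells; @param noise_sd per-cell Gaussian
#'   noise (0 = noiseless, Gaussian model only); @param noise_model
#'   "gaussian" adds noise on the normalized scale; "nb" draws per-cell
#'   negative-binomial counts with mean exp(profile) and dispersion
#'   \code{nb_dispersion}, then log-normalizes them; @param n_accel
#'   accelerated animals appended at the youngest age;
#'   @param acceleration_factor their effective age multiplier;
#'   @param seed seed.
#' @return list: \code{norm} (genes x cells), \code{cell_types},
#'   \code{animals} (per cell), \code{animal_meta} (animal, age_months,
#'   condition), \code{slopes} (per gene).
#' @export
simulate_age_profiles <- function(n_genes = 200L, n_slope_genes = 50L,
                                  ages_months = c(3, 6, 21),
                                  animals_per_age = 4L,
                                  cells_per_animal = 40L, noise_sd = 0.2,
                                  noise_model = c("gaussian", "nb"),
                                  nb_dispersion = 0.3,
                                  n_accel = 0L, acceleration_factor = 2,
                                  seed = 1L) {
  noise_model <- match.arg(noise_model)
  set.seed(seed)
  slopes <- numeric(n_genes)
  slopes[seq_len(n_slope_genes)] <- stats::runif(n_slope_genes, -2, 2)
  base <- stats::runif(n_genes, 1, 5)
  meta <- data.frame(
    animal = character(), age_months = numeric(), condition = character(),
    stringsAsFactors = FALSE
  )
  profs <- list()
  animals <- character()
  add_animal <- function(id, age, eff_age, cond) {
    mu <- base + slopes * log(eff_age)
    if (noise_model == "nb") {
      counts <- matrix(
        .rnb(n_genes * cells_per_animal, rep(exp(mu / 2), cells_per_animal),
             nb_dispersion),
        n_genes, cells_per_animal
      )
      cells <- as.matrix(normalize_log(counts + 1L))  # +1 keeps libsize > 0
    } else {
      cells <- matrix(mu, n_genes, cells_per_animal)
      if (noise_sd > 0) {
        cells <- cells + matrix(stats::rnorm(n_genes * cells_per_animal, 0,
                                             noise_sd),
                                n_genes, cells_per_animal)
      }
    }
    cells <- pmax(cells, 0)
    colnames(cells) <- sprintf("%s_c%03d", id, seq_len(cells_per_animal))
    profs[[id]] <<- cells
    animals <<- c(animals, rep(id, cells_per_animal))
    meta <<- rbind(meta, data.frame(animal = id, age_months = age,
                                    condition = cond,
                                    stringsAsFactors = FALSE))
  }
  for (age in ages_months) {
    for (a in seq_len(animals_per_age)) {
      add_animal(sprintf("m%g_%d", age, a), age, age, "WT")
    }
  }
  if (n_accel > 0L) {
    for (a in seq_len(n_accel)) {
      age <- min(ages_months)
      add_animal(sprintf("ad%d", a), age, age * acceleration_factor, "AD")
    }
  }
  norm <- do.call(cbind, profs)
  rownames(norm) <- sprintf("ag%03d", seq_len(n_genes))
  list(norm = norm, cell_types = rep("typeA", ncol(norm)),
       animals = animals, animal_meta = meta, slopes = slopes)
}

#' Build the full planted matrix bundle
#'
#' One call producing every downstream input with its truth: clustered
#' gene/exon matrices (with the exon-only twin pair), per-cell metadata
#' with planted abundance effects, spot mixtures, a module pseudobulk,
#' linked RNA/ATAC pseudo-cells, and age-structured profiles.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return named list of the component fixtures (each as documented in
#'   its simulator).
#' @export
make_matrix_fixture <- function(spec) {
  clusters <- simulate_cluster_counts(
    n_cells = max(spec$n_cells, 60L), n_genes = 100L,
    n_exons_per_gene = spec$n_exons_per_gene,
    n_clusters = spec$n_clusters, nb_dispersion = spec$nb_dispersion,
    seed = spec$seed
  )
  abundance <- simulate_abundance_cells(
    fold_changes = stats::setNames(spec$abundance_fold, "1"),
    seed = spec$seed
  )
  spots <- simulate_spot_mixtures(
    build_signature_matrix(clusters$gene, clusters$clusters),
    seed = spec$seed
  )
  modules <- simulate_module_matrix(
    n_modules = spec$n_modules, genes_per_module = spec$genes_per_module,
    seed = spec$seed
  )
  links <- simulate_linked_pseudocells(
    n_links = spec$n_links, n_decoys = spec$n_decoy_peaks, seed = spec$seed
  )
  ages <- simulate_age_profiles(
    ages_months = spec$ages_months, animals_per_age = spec$animals_per_age,
    n_slope_genes = spec$n_age_genes, seed = spec$seed
  )
  list(clusters = clusters, abundance = abundance, spots = spots,
       modules = modules, links = links, ages = ages)
}
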