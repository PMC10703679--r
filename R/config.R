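#' Pipeline configuration
#'
#' All numeric thresholds used by the pipeline live here; stage code contains
#' no literals. Defaults are the constants of the published protocol this
#' package implements: one-mismatch barcode correction, a 1,000 bp upstream
#' rescue window for 3'-biased reads, QC cutoffs (>30\% unassigned reads,
#' >20,000 UMIs, <200 genes), 30 gene-level + 10 exon-level principal
#' components for subclustering, marker cutoffs (2-fold, TPM > 50, FDR 5\%),
#' the 1e-5 abundance pseudocount with a twofold / q < 0.05 call and a
#' 20-cells-per-sex floor, the x100,000 log normalization, gene-module
#' filters (expression >= 1, fold change >= 5; UMAP cosine, min_dist 0.01,
#' n_neighbors 30; density thresholds rho = delta = 1), cis-regulatory
#' linkage settings (TPM > 10, +/-500 kb, permutation FDR < 0.01),
#' ATAC peak handling (score-per-million 1.3, summit +/-250 bp,
#' differential TPM > 20), the (0,10) motif-deviation rescale, and the
#' aging-clock pseudobulk size (~15 cells) with an 80/20 split.
#'
#' @param ... named overrides of any default listed below.
#' @return An object of class \code{pipeline_config}: a validated named list.
#' @examples
#' cfg <- pipeline_config()
#' cfg$qc_min_genes
#' pipeline_config(max_barcode_mismatch = 0)$max_barcode_mismatch
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    max_barcode_mismatch   = 1L,
    upstream_rescue_bp     = 1000L,
    qc_max_unassigned_frac = 0.30,
    qc_max_umis            = 20000L,
    qc_min_genes           = 200L,
    n_gene_pcs             = 30L,
    n_exon_pcs             = 10L,
    marker_fc_min          = 2.0,
    marker_tpm_min         = 50,
    de_fdr                 = 0.05,
    human_de_fc_min        = 1.5,
    abundance_pseudocount  = 1e-5,
    abundance_fc_min       = 2.0,
    abundance_min_cells_per_sex = 20L,
    abundance_sex_covariate = TRUE,
    norm_scale             = 1e5,
    gm_min_expr            = 1.0,
    gm_min_fc              = 5.0,
    gm_umap_min_dist       = 0.01,
    gm_umap_n_neighbors    = 30L,
    gm_rho                 = 1.0,
    gm_delta               = 1.0,
    cre_tpm_min            = 10,
    cre_window_bp          = 500000L,
    cre_fdr                = 0.01,
    cre_n_perm             = 10L,
    cre_promoter_bp        = 2000L,
    atac_spm_cutoff        = 1.3,
    atac_summit_pad_bp     = 250L,
    atac_diff_tpm_min      = 20,
    motif_rescale_range    = c(0, 10),
    clock_pseudobulk_k     = 15L,
    clock_train_frac       = 0.8,
    cluster_resolution     = 1.0,
    cluster_knn            = 20L,
    merge_min_sep          = 1.0,
    rng_seed               = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    }
    defaults[names(over)] <- over
  }
  cfg <- structure(defaults, class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  fracs <- c("qc_max_unassigned_frac", "de_fdr", "abundance_pseudocount",
             "cre_fdr", "clock_train_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(f, " must be a single fraction in [0,1]")
    }
  }
  counts <- c("max_barcode_mismatch", "upstream_rescue_bp", "qc_max_umis",
              "qc_min_genes", "n_gene_pcs", "n_exon_pcs",
              "abundance_min_cells_per_sex", "cre_window_bp", "cre_n_perm",
              "cre_promoter_bp", "atac_summit_pad_bp", "clock_pseudobulk_k",
              "cluster_knn", "gm_umap_n_neighbors")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop(f, " must be a single non-negative integer")
    }
  }
  if (cfg$motif_rescale_range[1] >= cfg$motif_rescale_range[2]) {
    stop("motif_rescale_range must be an increasing pair")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>", length(x), "settings\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ",")))
  }
  invisible(x)
}

#' Read / write a flat configuration file
#'
#' The on-disk format is one `key = value` pair per line, mirroring
#' \code{\link{pipeline_config}} field names; `#` starts a comment.
#'
#' @param path file path.
#' @param cfg a \code{pipeline_config}.
#' @return \code{read_pipeline_config} returns a \code{pipeline_config};
#'   \code{write_pipeline_config} returns \code{path} invisibly.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 1L)
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[2L], ",")[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else if (all(v %in% c("TRUE", "FALSE"))) as.logical(v) else v
  })
  names(vals) <- keys
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lines <- vapply(names(cfg), function(nm) {
    sprintf("%s = %s", nm, paste(format(cfg[[nm]], scientific = FALSE), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
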