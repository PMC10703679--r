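# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full read-level fixture: genome + whitelists + reads on disk
read_fixture <- function() {
  cached("read_fixture", function() {
    spec <- fixture_spec(seed = 42)
    wl <- make_fixture_whitelists(spec)
    gen <- make_genome_fixture(spec)
    dir <- file.path(tempdir(), "sciduet_read_fixture")
    fx <- make_read_fixture(spec, gen, wl, dir = dir)
    list(spec = spec, wl = wl, gen = gen, fx = fx, dir = dir)
  })
}

counted_fixture <- function() {
  cached("counted_fixture", function() {
    rf <- read_fixture()
    cnt <- count_features(rf$fx$paths$sam, rf$gen$annotation)
    c(rf, list(cnt = cnt))
  })
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# literal per-read re-derivation of the gene assignment rules, scanning
# every annotation row; intentionally independent of the package's
# vectorized implementation
oracle_assign <- function(frag, ann, upstream_bp = 1000) {
  g <- ann$genes
  on_chrom <- g$chrom == frag$chrom
  if (!any(on_chrom)) return(list(category = "discarded_no_chrom",
                                  gene_id = NA_character_))
  overlaps <- on_chrom & g$start < frag$end & g$end > frag$start
  sense <- overlaps & g$strand == frag$strand
  anti <- overlaps & g$strand != frag$strand
  tpe <- ifelse(g$strand == "+", g$end - 1, g$start)
  if (sum(sense) == 1) {
    return(list(category = "gene_unique", gene_id = g$gene_id[sense]))
  }
  if (sum(sense) > 1) {
    if (frag$primer == "dT") {
      mid <- (frag$start + frag$end) / 2
      ids <- g$gene_id[sense]
      d <- abs(mid - tpe[sense])
      return(list(category = "gene_3prime_tiebreak",
                  gene_id = sort(ids[d == min(d)])[1]))
    }
    return(list(category = "ambiguous", gene_id = NA_character_))
  }
  same <- on_chrom & g$strand == frag$strand
  if (frag$strand == "+") {
    up <- same & tpe < frag$start & tpe >= frag$start - upstream_bp
  } else {
    up <- same & tpe >= frag$end & tpe < frag$end + upstream_bp
  }
  if (any(up)) {
    mid <- (frag$start + frag$end) / 2
    ids <- g$gene_id[up]
    d <- abs(mid - tpe[up])
    return(list(category = "upstream_rescue",
                gene_id = sort(ids[d == min(d)])[1]))
  }
  if (sum(anti) == 1) {
    return(list(category = "antisense_rescue", gene_id = g$gene_id[anti]))
  }
  if (sum(anti) > 1) return(list(category = "ambiguous", gene_id = NA_character_))
  list(category = "discarded", gene_id = NA_character_)
}

# independent density-peak re-derivation used as the reference
# implementation on identical coordinates
oracle_density_peaks <- function(coords, rho_min, delta_min) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  dc <- stats::quantile(d[upper.tri(d)], 0.02, names = FALSE)
  if (dc == 0) dc <- min(d[d > 0])
  rho <- sapply(seq_len(n), function(i) sum(exp(-(d[i, -i] / dc)^2)))
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  parent <- integer(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (k == 1) {
      delta[i] <- max(d)
      parent[i] <- i
    } else {
      hi <- ord[1:(k - 1)]
      j <- hi[which.min(d[i, hi])]
      delta[i] <- d[i, j]
      parent[i] <- j
    }
  }
  centers <- which(rho > rho_min & delta > delta_min)
  lab <- integer(n)
  lab[centers] <- seq_along(centers)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (lab[i] == 0) lab[i] <- lab[parent[i]]
  }
  lab
}

# brute-force Benjamini-Hochberg from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
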