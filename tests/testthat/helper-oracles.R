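# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: everything is computed per base or by
# enumeration.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Per-base fragment depth, binned by summing within bins and dividing by
# bin_size, then normalized. Mirrors the track definition from first
# principles with an explicit base-level loop.
oracle_coverage <- function(fragments, chrom_len, bin_size, total_reads,
                            spike_factor = 1) {
  depth <- numeric(chrom_len)
  for (i in seq_along(fragments)) {
    s <- start(fragments)[i]
    e <- end(fragments)[i]
    depth[s:e] <- depth[s:e] + 1
  }
  nb <- ceiling(chrom_len / bin_size)
  vals <- numeric(nb)
  for (j in seq_len(nb)) {
    lo <- (j - 1L) * bin_size + 1L
    hi <- min(j * bin_size, chrom_len)
    vals[j] <- sum(depth[lo:hi]) / bin_size
  }
  vals * 1e6 / total_reads * spike_factor
}

# Per-base mean of a binned track over a 1-based closed window.
oracle_window_mean <- function(bin_values, bin_size, s, e) {
  base_vals <- rep(bin_values, each = bin_size)
  mean(base_vals[s:e])
}

# Per-base metagene vector: fixed flank bins then percent body bins then
# downstream flank, averaged base by base, reversed for minus-strand genes.
oracle_gene_vector <- function(bin_values, bin_size, chrom_len, gs, ge,
                               strand, flank = 4000, body_bins = 100) {
  base_vals <- rep(bin_values, each = bin_size)[seq_len(chrom_len)]
  nf <- flank %/% bin_size
  seg_mean <- function(s, e) {
    if (s < 1 || e > chrom_len) return(NA_real_)
    mean(base_vals[s:e])
  }
  left <- vapply(seq_len(nf), function(j)
    seg_mean(gs - flank + (j - 1) * bin_size,
             gs - flank + j * bin_size - 1), numeric(1))
  right <- vapply(seq_len(nf), function(j)
    seg_mean(ge + 1 + (j - 1) * bin_size, ge + j * bin_size), numeric(1))
  L <- ge - gs + 1
  cuts <- gs - 1 + floor((0:body_bins) * (L / body_bins))
  body <- vapply(seq_len(body_bins), function(i)
    seg_mean(cuts[i] + 1, cuts[i + 1]), numeric(1))
  v <- c(left, body, right)
  if (strand == "-") rev(v) else v
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# Benjamini-Hochberg from the definition: step-up over sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  run_min <- Inf
  for (i in rev(seq_len(n))) {
    run_min <- min(run_min, p[ord[i]] * n / i)
    adj[ord[i]] <- min(run_min, 1)
  }
  adj
}

# All-pairs edge-gap isolation oracle on plain coordinates (1-based
# closed); keeps index i when its minimal gap to every other interval on
# the same chrom is >= min_distance and it overlaps nothing.
oracle_isolated <- function(chrom, s, e, min_distance) {
  n <- length(s)
  keep <- logical(n)
  for (i in seq_len(n)) {
    gaps <- Inf
    for (j in seq_len(n)) {
      if (i == j || chrom[i] != chrom[j]) next
      g <- if (s[j] > e[i]) s[j] - e[i] - 1
           else if (s[i] > e[j]) s[i] - e[j] - 1
           else -1  # overlap
      gaps <- min(gaps, g)
    }
    keep[i] <- gaps >= min_distance
  }
  keep
}
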