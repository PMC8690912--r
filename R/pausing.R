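#' Pausing window definitions
#'
#' Three strand-oriented windows, expressed half-open in transcription-
#' direction coordinates: the promoter-proximal window `a` relative to the
#' TSS (default `[-30, 300)`), the gene-body window `b` from a TSS offset to
#' the TES (default `[300, TES)`, encoded with end `NA`), and the
#' termination window `c` relative to the TES (default `[0, 4000)`). The
#' traveling ratio is density(a)/density(b); the 3' pausing index is
#' density(c)/density(b).
#'
#' @param a,b,c Length-2 numeric vectors of half-open relative windows; an
#'   `NA` end in `b` means "through the TES".
#' @return A `PausingWindows` object.
#' @export
pausing_windows <- function(a = base::c(-30, 300), b = base::c(300, NA),
                            c = base::c(0, 4000)) {
  stopifnot(length(a) == 2L, length(b) == 2L, length(c) == 2L)
  if (a[1] >= a[2]) stop("window a is empty")
  if (!is.na(b[2]) && b[1] >= b[2]) stop("window b is empty")
  if (c[1] >= c[2]) stop("window c is empty")
  if (a[2] > b[1]) stop("window a must precede window b in transcription direction")
  structure(list(a = a, b = b, c = c), class = "PausingWindows")
}

# Genomic 1-based closed window for a half-open relative window anchored at
# `pos` (TSS or TES) in transcription direction; clipped to [1, chromlen].
# Returns c(NA, NA) when empty after clipping.
.anchor_window <- function(pos, str, rel1, rel2, chromlen) {
  if (str == "+") {
    s <- pos + rel1; e <- pos + rel2 - 1
  } else {
    s <- pos - rel2 + 1; e <- pos - rel1
  }
  s <- max(1, s); e <- min(chromlen, e)
  if (e < s) return(c(NA_real_, NA_real_))
  c(s, e)
}

.gene_ids <- function(genes) {
  if (!is.null(genes$gene_id)) as.character(genes$gene_id)
  else paste0("gene_", seq_along(genes))
}

# Shared worker: density ratio (num window)/(b window) per gene.
.pause_ratio <- function(track, genes, windows, eps, num = c("a", "c")) {
  num <- match.arg(num)
  str <- as.character(strand(genes))
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  chs <- as.character(seqnames(genes))
  ids <- .gene_ids(genes)
  out <- rep(NA_real_, length(genes))
  skipped <- character(0)
  for (i in seq_along(genes)) {
    len <- track$sizes[[chs[i]]]
    if (is.null(len)) stop("chromosome ", chs[i], " not in track")
    b2 <- if (is.na(windows$b[2])) width(genes)[i] else windows$b[2]
    if (b2 <= windows$b[1]) {
      skipped <- c(skipped, ids[i]); next
    }
    wb <- .anchor_window(tss[i], str[i], windows$b[1], b2, len)
    wn <- if (num == "a")
      .anchor_window(tss[i], str[i], windows$a[1], windows$a[2], len)
    else
      .anchor_window(tes[i], str[i], windows$c[1], windows$c[2], len)
    if (anyNA(wb) || anyNA(wn)) {
      skipped <- c(skipped, ids[i]); next
    }
    dn <- .wdens(track, chs[i], wn[1], wn[2])
    db <- .wdens(track, chs[i], wb[1], wb[2])
    out[i] <- (dn + eps) / (db + eps)
  }
  if (length(skipped))
    message(length(skipped), " gene(s) skipped (empty window after ",
            "orientation/clipping): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  stats::setNames(out, ids)
}

#' Traveling ratio per gene
#'
#' Ratio of Pol II density in the promoter-proximal window to density over
#' the remaining gene body; values above 1 indicate promoter-proximal
#' accumulation (pausing), and a genome-wide upward shift indicates reduced
#' pause release / productive elongation.
#'
#' @param track A `CoverageTrack` (typically total Pol II).
#' @param genes GRanges of gene models with `gene_id`. Genes whose body
#'   window is empty (too short) are skipped with a message and reported
#'   as `NA`.
#' @param windows A [pausing_windows()] object.
#' @param eps Per-base pseudocount added to both densities (default 0.01),
#'   keeping the ratio finite and positive on sparse data.
#' @return Named numeric vector of traveling ratios.
#' @export
traveling_ratio <- function(track, genes, windows = pausing_windows(),
                            eps = 0.01) {
  .pause_ratio(track, genes, windows, eps, num = "a")
}

#' 3' pausing index per gene
#'
#' Ratio of Pol II density in the transcription-termination window
#' (downstream of the TES) to the gene-body density. Elevated values mean
#' polymerase accumulating at the 3' end, i.e. delayed termination or an
#' elongation defect in the termination region.
#'
#' @inheritParams traveling_ratio
#' @return Named numeric vector of 3' pausing indices.
#' @export
pausing_index_3prime <- function(track, genes, windows = pausing_windows(),
                                 eps = 0.01) {
  .pause_ratio(track, genes, windows, eps, num = "c")
}

#' Average signal over the extended gene territory
#'
#' Mean density from `flank` bases upstream of the TSS to `flank` bases
#' downstream of the TES (clipped to the chromosome); the quantity used to
#' rank genes into confidence tiers.
#'
#' @inheritParams traveling_ratio
#' @param flank Flank width in bases (default 4000).
#' @return Named numeric vector.
#' @export
average_signal <- function(track, genes, flank = 4000) {
  chs <- as.character(seqnames(genes))
  ids <- .gene_ids(genes)
  out <- vapply(seq_along(genes), function(i) {
    len <- track$sizes[[chs[i]]]
    if (is.null(len)) stop("chromosome ", chs[i], " not in track")
    .wdens(track, chs[i], max(1, start(genes)[i] - flank),
           min(len, end(genes)[i] + flank))
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Rank-based confidence tiers from average signal
#'
#' Genes are ranked by descending average ChIP signal (ties broken by gene
#' id, stable) and split into high (top `boundaries[1]` fraction),
#' intermediate (up to `boundaries[2]`) and low (remainder) tiers. Tier
#' sizes use the ceiling rule: with N genes, `high = ceiling(b1 * N)` and
#' `high + intermediate = ceiling(b2 * N)`, which reproduces e.g.
#' 515 -> 155/103/257 at the default 30%/50% boundaries.
#'
#' @param avg_signals Named numeric vector of per-gene average signal.
#' @param boundaries Cumulative rank fractions for the high and
#'   high+intermediate cuts (default `c(0.30, 0.50)`).
#' @return Factor (levels high/intermediate/low) named and ordered as the
#'   input.
#' @export
assign_tiers <- function(avg_signals, boundaries = c(0.30, 0.50)) {
  n <- length(avg_signals)
  if (n < 1L) stop("need at least one gene")
  stopifnot(length(boundaries) == 2L, boundaries[1] > 0,
            boundaries[1] <= boundaries[2], boundaries[2] <= 1)
  ids <- names(avg_signals) %||% as.character(seq_len(n))
  ord <- order(-avg_signals, ids)
  # round before ceiling: p * N may sit a float ulp above an exact integer
  n_high <- min(n, as.integer(ceiling(round(boundaries[1] * n, 6))))
  n_cum <- min(n, as.integer(ceiling(round(boundaries[2] * n, 6))))
  tier <- character(n)
  tier[ord[seq_len(n_high)]] <- "high"
  if (n_cum > n_high)
    tier[ord[seq.int(n_high + 1L, n_cum)]] <- "intermediate"
  if (n > n_cum)
    tier[ord[seq.int(n_cum + 1L, n)]] <- "low"
  factor(stats::setNames(tier, ids),
         levels = c("high", "intermediate", "low"))
}

#' Per-gene pausing metrics table
#'
#' Computes traveling ratio, 3' pausing index, average signal and
#' confidence tier for a gene cohort in one pass.
#'
#' @inheritParams traveling_ratio
#' @param flank Flank for [average_signal()] (default 4000).
#' @param boundaries Tier boundaries for [assign_tiers()].
#' @return Data frame with columns gene_id, tr, pi3, avg_signal, tier.
#' @export
pausing_metrics <- function(track, genes, windows = pausing_windows(),
                            eps = 0.01, flank = 4000,
                            boundaries = c(0.30, 0.50)) {
  avg <- average_signal(track, genes, flank)
  data.frame(gene_id = .gene_ids(genes),
             tr = unname(traveling_ratio(track, genes, windows, eps)),
             pi3 = unname(pausing_index_3prime(track, genes, windows, eps)),
             avg_signal = unname(avg),
             tier = unname(assign_tiers(avg, boundaries)))
}

#' Compare per-gene pausing metrics between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on two sets of per-gene
#' values (traveling ratios or pausing indices). Exact p-values are used
#' for small tie-free samples; otherwise the tie-corrected normal
#' approximation.
#'
#' @param values_a,values_b Numeric vectors (>= 3 values each); `NA`s are
#'   dropped.
#' @return List with `statistic` (the Mann-Whitney U of `values_a`),
#'   `p_value`, `median_a`, `median_b` and `direction`
#'   ("a_higher"/"b_higher"/"equal") by median.
#' @export
compare_conditions <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("need at least 3 values per condition")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  ma <- stats::median(values_a)
  mb <- stats::median(values_b)
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       median_a = ma, median_b = mb,
       direction = if (ma > mb) "a_higher"
                   else if (ma < mb) "b_higher" else "equal")
}
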