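#' Per-gene signal vector on the metagene coordinate system
#'
#' Samples a coverage track for one gene on the common metagene axis: a
#' fixed upstream flank (genomic bins of the track's bin size, `flank /
#' bin_size` of them), a percent-scaled gene body (`body_bins` equal-length
#' sub-intervals, each summarized by its length-weighted mean density), and
#' a fixed downstream flank. Vectors are always oriented 5' to 3' of the
#' gene: index 1 is `flank` bases upstream of the TSS regardless of strand.
#' Flank bins extending past a chromosome end are returned as `NA`
#' (missing), not zero, so they can be excluded from averages.
#'
#' @param track A `CoverageTrack`.
#' @param gene Single-range GRanges gene model (strand + or -).
#' @param flank Flank width in bases (default 4000); must be a multiple of
#'   the track bin size.
#' @param body_bins Number of percent-scaled body bins (default 100). The
#'   gene must be at least `body_bins` bases long.
#' @return Numeric vector of length `2 * flank/bin_size + body_bins`.
#' @export
gene_signal_vector <- function(track, gene, flank = 4000, body_bins = 100) {
  stopifnot(length(gene) == 1L)
  b <- track$bin_size
  if (flank %% b != 0)
    stop("flank must be a multiple of the track bin size")
  L <- width(gene)
  if (L < body_bins)
    stop("gene ", gene$gene_id, " shorter (", L, " bp) than body_bins (",
         body_bins, ")")
  str <- as.character(strand(gene))
  if (!str %in% c("+", "-")) stop("gene strand must be + or -")
  ch <- as.character(seqnames(gene))
  len <- track$sizes[[ch]]
  if (is.null(len)) stop("chromosome ", ch, " not in track")
  nf <- flank %/% b
  gs <- start(gene); ge <- end(gene)

  lst <- (gs - flank) + (seq_len(nf) - 1L) * b
  rst <- (ge + 1L) + (seq_len(nf) - 1L) * b
  cuts <- gs - 1 + floor((0:body_bins) * (L / body_bins))
  st <- c(lst, cuts[-(body_bins + 1L)] + 1, rst)
  en <- c(lst + b - 1L, cuts[-1L], rst + b - 1L)
  out_of_chrom <- st < 1L | en > len
  st[out_of_chrom] <- NA_real_
  en[out_of_chrom] <- NA_real_
  v <- .wdens_many(track$bins[[ch]], b, st, en)
  if (str == "-") v <- rev(v)
  v
}

#' Signal matrix over a gene cohort
#'
#' One [gene_signal_vector()] row per gene, in the input gene order.
#' Columns are labelled `u<i>` (upstream flank, 5' to 3'), `b<i>` (body
#' percent bins) and `d<i>` (downstream flank).
#'
#' @inheritParams gene_signal_vector
#' @param genes GRanges of gene models with `gene_id`.
#' @return Numeric matrix, rownames = gene ids.
#' @export
signal_matrix <- function(track, genes, flank = 4000, body_bins = 100) {
  if (!length(genes)) stop("no genes supplied")
  nf <- flank %/% track$bin_size
  m <- t(vapply(seq_along(genes), function(i)
    gene_signal_vector(track, genes[i], flank, body_bins),
    numeric(2L * nf + body_bins)))
  rownames(m) <- genes$gene_id
  colnames(m) <- c(paste0("u", seq_len(nf)), paste0("b", seq_len(body_bins)),
                   paste0("d", seq_len(nf)))
  attr(m, "flank") <- flank
  attr(m, "body_bins") <- body_bins
  attr(m, "bin_size") <- track$bin_size
  m
}

#' Aggregate a signal matrix into a metagene profile
#'
#' Column-wise mean (or median) across genes, ignoring missing entries
#' (flank bins clipped at chromosome ends).
#'
#' @param mat Matrix from [signal_matrix()].
#' @param aggregator "mean" (average occupancy, the default) or "median".
#' @return Data frame with `bin` (column label), `region`
#'   (upstream/body/downstream), `position` (bp relative to TSS/TES for
#'   flanks, percent for body) and `value`; `n_genes` and `aggregator` are
#'   attached as attributes.
#' @export
aggregate_profile <- function(mat, aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  if (is.null(dim(mat)) || nrow(mat) == 0L) stop("empty signal matrix")
  fun <- if (aggregator == "mean") function(x) mean(x, na.rm = TRUE)
         else function(x) stats::median(x, na.rm = TRUE)
  vals <- apply(mat, 2L, fun)
  lab <- colnames(mat)
  region <- factor(substr(lab, 1, 1), levels = c("u", "b", "d"),
                   labels = c("upstream", "body", "downstream"))
  idx <- as.integer(substring(lab, 2))
  flank <- attr(mat, "flank") %||% 4000
  body_bins <- attr(mat, "body_bins") %||% sum(region == "body")
  bsz <- attr(mat, "bin_size") %||% 20
  position <- ifelse(region == "upstream", -flank + (idx - 1L) * bsz,
              ifelse(region == "body", (idx - 0.5) / body_bins * 100,
                     (idx - 1L) * bsz))
  out <- data.frame(bin = lab, region = region, position = position,
                    value = unname(vals))
  attr(out, "n_genes") <- nrow(mat)
  attr(out, "aggregator") <- aggregator
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metagene profile of a track over a gene cohort
#'
#' Convenience wrapper: [signal_matrix()] then [aggregate_profile()].
#'
#' @inheritParams signal_matrix
#' @inheritParams aggregate_profile
#' @return See [aggregate_profile()].
#' @export
metagene_profile <- function(track, genes, flank = 4000, body_bins = 100,
                             aggregator = "mean") {
  aggregate_profile(signal_matrix(track, genes, flank, body_bins),
                    aggregator = aggregator)
}
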