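#' Extend reads toward the fragment interior
#'
#' Single-end ChIP-seq reads mark only the 5' end of each sequenced
#' fragment; extending every read to the expected fragment length in its
#' strand direction recovers an approximation of the full fragment. A +
#' read keeps its start and grows 3'-wards, a - read keeps its end and
#' grows 5'-wards (in genomic coordinates). Reads already at least
#' `target_length` long are returned unchanged; results are clipped to the
#' chromosome.
#'
#' @param reads GRanges of aligned reads with strand + or -.
#' @param target_length Fragment length in bases (default 150).
#' @param sizes Named chromosome lengths used for clipping.
#' @return GRanges of extended fragments (strand preserved).
#' @export
extend_reads <- function(reads, target_length = 150, sizes = NULL) {
  if (!length(reads)) return(reads)
  str <- as.character(strand(reads))
  if (any(!str %in% c("+", "-")))
    stop("all reads must have strand + or - for extension")
  out <- suppressWarnings(
    resize(reads, width = pmax(width(reads), target_length), fix = "start"))
  # clipping at chromosome bounds is routine here, so it stays silent
  if (!is.null(sizes)) {
    sizes <- chrom_sizes(sizes)
    missing_chrom <- setdiff(unique(as.character(seqnames(out))),
                             names(sizes))
    if (length(missing_chrom))
      stop("chromosome(s) not in chrom sizes: ",
           paste(missing_chrom, collapse = ", "))
    suppressWarnings({
      seqlevels(out) <- names(sizes)
      seqlengths(out) <- unname(sizes)
    })
    out <- trim(out)
  } else if (any(start(out) < 1L)) {
    out <- trim(GRanges(seqnames(out),
                        IRanges(pmax(start(out), 1L), end(out)),
                        strand = strand(out)))
  }
  out
}

#' Spike-in scaling factor
#'
#' Exogenous (e.g. Drosophila) chromatin added in fixed proportion before
#' immunoprecipitation lets samples be rescaled onto a common spike depth:
#' the factor is `reference_spike_reads / sample_spike_reads`, so samples
#' that captured more spike reads than the reference are scaled down.
#'
#' @param sample_spike_reads Spike-genome read count of the sample.
#' @param reference_spike_reads Spike-genome read count of the reference.
#' @return Positive multiplier applied to the sample's coverage track.
#' @export
spike_in_factor <- function(sample_spike_reads, reference_spike_reads) {
  if (sample_spike_reads <= 0 || reference_spike_reads <= 0)
    stop("spike-in read counts must be positive")
  reference_spike_reads / sample_spike_reads
}

.new_track <- function(bins, bin_size, sizes, total_reads, spike_factor,
                       kind = "density", pseudocount = NA_real_) {
  structure(list(bins = bins,
                 bin_size = as.integer(bin_size),
                 sizes = sizes,
                 total_reads = total_reads,
                 per_million_factor = if (kind == "density")
                   1e6 / total_reads else NA_real_,
                 spike_factor = spike_factor,
                 kind = kind,
                 pseudocount = pseudocount),
            class = "CoverageTrack")
}

#' Binned, normalized coverage from fragment intervals
#'
#' Accumulates per-base fragment depth, sums it within consecutive
#' `bin_size`-bp bins, divides by `bin_size`, and scales by
#' `1e6 / total_reads * spike_factor`. Each full bin therefore holds the
#' mean per-base depth in reads-per-million (times the spike factor);
#' partial fragment/bin overlaps contribute proportionally. The
#' conservation identity
#' `sum(bins * bin_size) = 1e6/total_reads * spike_factor * sum(width(fragments))`
#' holds exactly for every input.
#'
#' @param fragments GRanges of (extended) fragments.
#' @param sizes Named chromosome lengths; defines the binning grid.
#' @param bin_size Bin width in bases (default 20).
#' @param total_reads Mapped-read count used for the per-million factor;
#'   defaults to `length(fragments)` (1 when empty).
#' @param spike_factor Spike-in multiplier (default 1).
#' @return A `CoverageTrack`: list with per-chromosome numeric bin vectors
#'   (`bins`), `bin_size`, `sizes` and normalization metadata.
#' @export
compute_coverage <- function(fragments, sizes, bin_size = 20,
                             total_reads = max(length(fragments), 1L),
                             spike_factor = 1) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (total_reads <= 0) stop("total_reads must be positive")
  if (spike_factor <= 0) stop("spike_factor must be positive")
  sizes <- chrom_sizes(sizes)
  fragments <- .apply_sizes(granges(fragments), sizes, "fragment")
  cov <- coverage(fragments)
  norm <- 1e6 / total_reads * spike_factor
  bins <- lapply(names(sizes), function(ch) {
    len <- sizes[[ch]]
    nb <- as.integer(ceiling(len / bin_size))
    st <- seq.int(1L, by = bin_size, length.out = nb)
    en <- pmin(st + bin_size - 1L, len)
    v <- Views(cov[[ch]], start = st, end = en)
    as.numeric(viewSums(v)) / bin_size * norm
  })
  names(bins) <- names(sizes)
  .new_track(bins, bin_size, sizes, total_reads, spike_factor)
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack (", x$kind, "): ", length(x$bins),
      " chromosome(s), bin size ", x$bin_size, " bp\n", sep = "")
  if (x$kind == "density")
    cat("  normalization: ", format(x$per_million_factor, digits = 4),
        " per-million x spike ", format(x$spike_factor, digits = 4),
        " (", x$total_reads, " reads)\n", sep = "")
  else
    cat("  ratio track, pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

# Vectorized length-weighted bin-value means over many windows of one
# chromosome, via a base-level prefix sum: S(x) = signal summed over bases
# 1..x expands each bin value to its bases. NA windows stay NA.
.wdens_many <- function(vals, bin_size, s, e) {
  C <- c(0, cumsum(vals))
  S <- function(x) {
    k <- x %/% bin_size
    r <- x - k * bin_size
    extra <- numeric(length(x))
    nz <- !is.na(r) & r > 0
    extra[nz] <- vals[k[nz] + 1L] * r[nz]
    C[k + 1L] * bin_size + extra
  }
  (S(e) - S(s - 1)) / (e - s + 1)
}

# Length-weighted mean of bin values over 1-based closed [s, e] on chrom.
.wdens <- function(track, chrom, s, e) {
  if (is.na(s) || is.na(e) || e < s) stop("empty or invalid window")
  vals <- track$bins[[chrom]]
  if (is.null(vals)) stop("chromosome ", chrom, " not in track")
  b <- track$bin_size
  i0 <- (s - 1L) %/% b
  i1 <- (e - 1L) %/% b
  idx <- i0:i1
  bs <- idx * b + 1
  be <- (idx + 1) * b
  w <- pmin(e, be) - pmax(s, bs) + 1
  sum(w * vals[idx + 1L]) / (e - s + 1)
}

#' Mean normalized signal density over a window
#'
#' Length-weighted mean of bin values across the window; bins only partly
#' inside the window are weighted by their overlap, so the result equals a
#' per-base average of the track expanded to base resolution.
#'
#' @param track A `CoverageTrack`.
#' @param window GRanges of windows (any strand; density is orientation
#'   free), or a single chromosome name when `start`/`end` are given.
#' @param start,end Optional 1-based closed coordinates used with a
#'   chromosome-name `window`.
#' @return Numeric vector of densities (normalized signal per base).
#' @export
window_density <- function(track, window, start = NULL, end = NULL) {
  if (is.character(window)) {
    stopifnot(length(window) == 1L, !is.null(start), !is.null(end))
    return(.wdens(track, window, start, end))
  }
  if (!length(window)) return(numeric(0))
  vapply(seq_along(window), function(i)
    .wdens(track, as.character(seqnames(window))[i],
           BiocGenerics::start(window)[i], BiocGenerics::end(window)[i]),
    numeric(1))
}

#' Bin-wise factor occupancy normalized to Pol II
#'
#' Computes `(factor + pseudocount) / (polII + pseudocount)` per bin, the
#' standard way to ask whether a factor is enriched relative to the local
#' polymerase density rather than in absolute signal. The pseudocount keeps
#' empty bins defined (0/0 -> 1).
#'
#' @param factor_track,polii_track `CoverageTrack`s on identical grids
#'   (same chromosomes, lengths and bin size).
#' @param pseudocount Added to both numerator and denominator (default 0.1).
#' @return A ratio-kind `CoverageTrack`.
#' @export
normalized_occupancy <- function(factor_track, polii_track,
                                 pseudocount = 0.1) {
  if (factor_track$bin_size != polii_track$bin_size)
    stop("bin sizes differ between tracks")
  if (!identical(factor_track$sizes, polii_track$sizes))
    stop("chromosome grids differ between tracks")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  bins <- mapply(function(f, p) (f + pseudocount) / (p + pseudocount),
                 factor_track$bins, polii_track$bins, SIMPLIFY = FALSE)
  .new_track(bins, factor_track$bin_size, factor_track$sizes,
             total_reads = NA_real_, spike_factor = 1,
             kind = "ratio", pseudocount = pseudocount)
}

#' Construct a CoverageTrack from explicit bin values
#'
#' Mainly for building reference tracks in examples and tests; `values`
#' must contain one numeric vector per chromosome with
#' `ceiling(length / bin_size)` entries.
#'
#' @param values Named list of per-chromosome bin-value vectors.
#' @param bin_size Bin width in bases.
#' @param sizes Named chromosome lengths.
#' @return A density-kind `CoverageTrack`.
#' @export
as_coverage_track <- function(values, bin_size, sizes) {
  sizes <- chrom_sizes(sizes)
  stopifnot(identical(sort(names(values)), sort(names(sizes))))
  for (ch in names(sizes)) {
    nb <- as.integer(ceiling(sizes[[ch]] / bin_size))
    if (length(values[[ch]]) != nb)
      stop("chromosome ", ch, " needs ", nb, " bins, got ",
           length(values[[ch]]))
  }
  .new_track(values[names(sizes)], bin_size, sizes,
             total_reads = 1e6, spike_factor = 1)
}

#' Write a CoverageTrack as bedGraph
#'
#' Runs of equal bin values are merged; zero-valued runs are omitted.
#' Coordinates follow the bedGraph convention (0-based half-open).
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @param digits Significant digits for values (default 6).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- track$bin_size
  for (ch in names(track$bins)) {
    v <- signif(track$bins[[ch]], digits)
    r <- rle(v)
    en <- cumsum(r$lengths)
    st <- en - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    df <- data.frame(ch, st[keep] * b,
                     pmin(en[keep] * b, track$sizes[[ch]]), r$values[keep])
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
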