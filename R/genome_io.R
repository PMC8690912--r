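#' Read a chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bases.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome names in ", path)
  if (any(tab$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(tab$length, tab$chrom)
}

#' Build a chrom-sizes vector
#'
#' @param lengths Integer lengths, named by chromosome.
#' @return Validated named integer vector.
#' @export
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths))) stop("duplicate chromosome names")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(as.integer(lengths), names(lengths))
}

# Attach seqlengths (clipping out-of-range ranges with a warning) to a GRanges.
.apply_sizes <- function(gr, sizes, what = "interval") {
  if (is.null(sizes)) return(gr)
  missing_chrom <- setdiff(unique(as.character(seqnames(gr))), names(sizes))
  if (length(missing_chrom))
    stop("chromosome(s) not in chrom sizes: ",
         paste(missing_chrom, collapse = ", "))
  suppressWarnings({
    seqlevels(gr) <- names(sizes)
    seqlengths(gr) <- unname(sizes)
  })
  bad <- start(gr) < 1L | end(gr) > seqlengths(gr)[as.character(seqnames(gr))]
  if (any(bad)) {
    warning(sum(bad), " ", what, "(s) extend past chromosome ends; clipped")
    gr <- trim(gr)
  }
  gr
}

.parse_bed_fields <- function(lines, path, min_fields) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate space-separated BED
  ws <- lengths(fields) < min_fields
  fields[ws] <- strsplit(lines[ws], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop("malformed BED line ", which(nf < min_fields)[1], " in ", path,
         ": expected >= ", min_fields, " fields")
  fields
}

.bed_core <- function(fields, path, strand_required = FALSE) {
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(s0) | is.na(e0) | s0 < 0L | e0 <= s0
  if (any(bad))
    stop("malformed BED line ", which(bad)[1], " in ", path,
         ": start/end invalid")
  strand <- rep(".", length(fields))
  has6 <- lengths(fields) >= 6L
  strand[has6] <- vapply(fields[has6], `[`, "", 6L)
  badstr <- !strand %in% c("+", "-", ".")
  if (any(badstr))
    stop("unknown strand '", strand[which(badstr)[1]], "' on line ",
         which(badstr)[1], " in ", path)
  if (strand_required && any(strand == "."))
    stop("strand required but missing on line ", which(strand == ".")[1],
         " in ", path)
  list(chrom = chrom, start = s0 + 1L, end = e0,
       strand = ifelse(strand == ".", "*", strand))
}

#' Read a BED6 file as a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention on read; [write_bed6()] inverts the conversion exactly.
#'
#' @param path BED file path (3-6 columns, tab or space separated).
#' @param sizes Optional named chromosome lengths; ranges past chromosome
#'   ends are clipped with a warning.
#' @param strand_required Error when the strand column is absent or ".".
#' @return GRanges with `name` and `score` metadata columns.
#' @export
read_bed6 <- function(path, sizes = NULL, strand_required = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(.apply_sizes(GRanges(), sizes))
  fields <- .parse_bed_fields(lines, path, 3L)
  core <- .bed_core(fields, path, strand_required)
  nm <- rep(NA_character_, length(fields))
  sc <- rep(0, length(fields))
  has4 <- lengths(fields) >= 4L
  nm[has4] <- vapply(fields[has4], `[`, "", 4L)
  has5 <- lengths(fields) >= 5L
  sc[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5L)))
  sc[is.na(sc)] <- 0
  gr <- GRanges(core$chrom, IRanges(core$start, core$end),
                strand = core$strand, name = nm, score = sc)
  .apply_sizes(gr, sizes)
}

#' Write a GRanges as BED6
#'
#' @param gr GRanges; `name`/`score` metadata columns are used when present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
        else paste0("feature_", seq_along(gr))
  nm[is.na(nm)] <- "."
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = nm, score = sc, strand = str)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.read_genes_bed <- function(path, sizes, bed12 = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(GRanges())
  fields <- .parse_bed_fields(lines, path, if (bed12) 12L else 6L)
  core <- .bed_core(fields, path, strand_required = TRUE)
  gene_id <- vapply(fields, `[`, "", 4L)
  gr <- GRanges(core$chrom, IRanges(core$start, core$end),
                strand = core$strand, gene_id = gene_id)
  if (bed12) {
    nblk <- as.integer(vapply(fields, `[`, "", 10L))
    bsz <- strsplit(vapply(fields, `[`, "", 11L), ",", fixed = TRUE)
    bst <- strsplit(vapply(fields, `[`, "", 12L), ",", fixed = TRUE)
    exons <- lapply(seq_along(fields), function(i) {
      sizes_i <- as.integer(bsz[[i]])[seq_len(nblk[i])]
      starts_i <- as.integer(bst[[i]])[seq_len(nblk[i])]
      IRanges(start = core$start[i] + starts_i, width = sizes_i)
    })
    mcols(gr)$exons <- IRangesList(exons)
  }
  gr
}

.read_genes_gtf <- function(path) {
  gff <- rtracklayer::import(path)
  type <- as.character(gff$type)
  sel <- gff[type == "gene"]
  if (!length(sel)) sel <- gff[type == "transcript"]
  if (!length(sel)) stop("no gene or transcript records in ", path)
  id <- sel$gene_id
  if (is.null(id)) id <- sel$ID
  if (is.null(id)) stop("no gene_id attribute in ", path)
  GRanges(seqnames(sel), ranges(sel), strand = strand(sel),
          gene_id = as.character(id))
}

#' Read gene models from an annotation file
#'
#' Accepts BED6, BED12 (exon blocks kept in an `exons` metadata column) or
#' GTF/GFF (records of type "gene", falling back to "transcript"). Output is
#' sorted deterministically by chromosome, start, then gene id. The TSS of a
#' gene is its 5' anchor ([gene_tss()]) and the TES its 3' anchor
#' ([gene_tes()]); both are derived from the interval and strand, never
#' stored.
#'
#' @param path Annotation file path.
#' @param format One of "auto", "bed6", "bed12", "gtf". "auto" keys on the
#'   file extension (.gtf/.gff -> gtf) and field count (12 -> bed12).
#' @param sizes Optional named chromosome lengths for validation/clipping.
#' @return GRanges with a `gene_id` metadata column.
#' @export
read_genes <- function(path, format = c("auto", "bed6", "bed12", "gtf"),
                       sizes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("gtf", "gff", "gff3")) "gtf" else {
      first <- readLines(path, n = 50L)
      first <- first[nzchar(first) & !startsWith(first, "#") &
                       !startsWith(first, "track")]
      nf <- if (length(first)) length(strsplit(first[1], "[ \t]+")[[1]]) else 6L
      if (nf >= 12L) "bed12" else "bed6"
    }
  }
  gr <- switch(format,
               bed6 = .read_genes_bed(path, sizes, bed12 = FALSE),
               bed12 = .read_genes_bed(path, sizes, bed12 = TRUE),
               gtf = .read_genes_gtf(path))
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene records must carry + or - strand")
  gr <- .apply_sizes(gr, sizes, "gene")
  ord <- order(as.character(seqnames(gr)), start(gr), gr$gene_id)
  gr[ord]
}

#' Strand-aware gene anchors
#'
#' The transcription start site is the low coordinate of a + gene and the
#' high coordinate of a - gene; the transcription end site is the opposite
#' anchor.
#'
#' @param genes GRanges of gene models.
#' @return Integer vector of 1-based anchor positions.
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Select genes isolated from all other annotations
#'
#' Keeps genes whose closest-edge gap to every other annotation on the same
#' chromosome is at least `min_distance` bases; genes that overlap or abut
#' another annotation are always excluded. Used to build clean metagene
#' cohorts where flanking windows cannot pick up a neighbour's signal.
#'
#' @param genes GRanges of candidate gene models.
#' @param min_distance Minimum edge-to-edge gap in bases (default 4000).
#' @param extra_annotations Optional GRanges of further annotation intervals
#'   (snRNA, snoRNA, tRNA, ...) considered as neighbours in addition to the
#'   gene set itself. A gene is never its own neighbour.
#' @return The isolated subset of `genes`, original order preserved.
#' @export
select_isolated_genes <- function(genes, min_distance = 4000,
                                  extra_annotations = NULL) {
  if (!length(genes)) return(genes)
  dist <- rep(Inf, length(genes))
  hits <- distanceToNearest(genes, ignore.strand = TRUE)
  dist[queryHits(hits)] <- mcols(hits)$distance
  overl <- countOverlaps(genes, genes, ignore.strand = TRUE) > 1L
  if (!is.null(extra_annotations) && length(extra_annotations)) {
    h2 <- distanceToNearest(genes, extra_annotations, ignore.strand = TRUE)
    dist[queryHits(h2)] <- pmin(dist[queryHits(h2)], mcols(h2)$distance)
    overl <- overl | overlapsAny(genes, extra_annotations, ignore.strand = TRUE)
  }
  genes[dist >= min_distance & !overl]
}

#' Read peak calls (BED or narrowPeak)
#'
#' For 10-column narrowPeak input the summit offset (column 10, -1 when
#' absent) is stored as an absolute `summit` position used as the peak
#' anchor by [annotate_peaks()].
#'
#' @param path Peak file path.
#' @param sizes Optional chromosome lengths.
#' @return GRanges with `name`, `score` and (narrowPeak) `summit` columns.
#' @export
read_peaks <- function(path, sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(GRanges())
  fields <- .parse_bed_fields(lines, path, 3L)
  gr <- read_bed6(path, sizes = sizes)
  if (any(mcols(gr)$score < 0))
    stop("negative peak score in ", path)
  if (all(lengths(fields) >= 10L)) {
    off <- as.integer(vapply(fields, `[`, "", 10L))
    summit <- ifelse(off >= 0L, start(gr) + off, NA_integer_)
    mcols(gr)$summit <- summit
  }
  gr
}

#' Remove peaks overlapping blacklisted regions
#'
#' A peak overlapping any blacklist interval by at least one base is
#' dropped; survivors keep their input order. Commonly used with the ENCODE
#' consortium blacklist to discard anomalous high-signal artifact regions.
#'
#' @param peaks GRanges of peaks.
#' @param blacklist GRanges of regions to exclude.
#' @return Filtered GRanges, a subset of `peaks`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (!length(peaks) || !length(blacklist)) return(peaks)
  peaks[!overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}
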