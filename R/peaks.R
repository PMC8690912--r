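#' Annotate peaks to genomic features
#'
#' Assigns each peak exactly one feature class by the precedence
#' promoter > three_prime > exon > intron > intergenic. The peak anchor is
#' its summit when a `summit` metadata column is present (narrowPeak),
#' otherwise its midpoint. A peak is a promoter peak when its anchor lies
#' within `promoter_dist` of the nearest TSS, a three-prime peak within
#' `three_prime_dist` of the nearest TES; otherwise an anchor inside a gene
#' body is exonic if the gene carries an exon model (`exons` metadata
#' column from BED12) overlapping the anchor, intronic if not (genes
#' without exon models yield intron calls for body hits); anything else is
#' intergenic. The nearest gene is chosen by anchor-to-TSS distance, ties
#' broken by gene id, so gene input order never changes the result.
#'
#' @param peaks GRanges of peaks (`name`, `score`, optional `summit`).
#' @param genes GRanges of gene models with `gene_id` (optional `exons`).
#' @param promoter_dist Maximum anchor-to-TSS distance for a promoter call
#'   (default 1000).
#' @param three_prime_dist Maximum anchor-to-TES distance for a 3'-end call
#'   (default 1000).
#' @return Data frame with columns peak_name, chrom, start, end, anchor,
#'   feature, nearest_gene, distance_to_tss (signed, negative upstream of
#'   the TSS in transcription direction).
#' @export
annotate_peaks <- function(peaks, genes, promoter_dist = 1000,
                           three_prime_dist = 1000) {
  if (!length(peaks))
    return(data.frame(peak_name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      anchor = integer(0), feature = character(0),
                      nearest_gene = character(0),
                      distance_to_tss = numeric(0)))
  anchor <- if (!is.null(mcols(peaks)$summit) &&
                !all(is.na(mcols(peaks)$summit)))
    ifelse(is.na(mcols(peaks)$summit),
           (start(peaks) + end(peaks)) %/% 2L, mcols(peaks)$summit)
  else (start(peaks) + end(peaks)) %/% 2L
  pk_chr <- as.character(seqnames(peaks))
  ids <- .gene_ids(genes)
  g_chr <- as.character(seqnames(genes))
  g_str <- as.character(strand(genes))
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  exons <- mcols(genes)$exons
  nm <- if (!is.null(mcols(peaks)$name)) as.character(mcols(peaks)$name)
        else paste0("peak_", seq_along(peaks))
  nm[is.na(nm)] <- paste0("peak_", which(is.na(nm)))

  feature <- character(length(peaks))
  nearest_gene <- character(length(peaks))
  dist_tss <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    on_chr <- which(g_chr == pk_chr[i])
    if (!length(on_chr)) {
      feature[i] <- "intergenic"
      nearest_gene[i] <- NA_character_
      dist_tss[i] <- NA_real_
      next
    }
    a <- anchor[i]
    d_abs <- abs(a - tss[on_chr])
    pick <- on_chr[order(d_abs, ids[on_chr])[1L]]
    nearest_gene[i] <- ids[pick]
    # signed distance: positive downstream of the TSS in transcription dir
    dist_tss[i] <- if (g_str[pick] == "+") a - tss[pick] else tss[pick] - a
    if (min(d_abs) <= promoter_dist) {
      feature[i] <- "promoter"
    } else if (min(abs(a - tes[on_chr])) <= three_prime_dist) {
      feature[i] <- "three_prime"
    } else {
      inside <- on_chr[start(genes)[on_chr] <= a & a <= end(genes)[on_chr]]
      if (!length(inside)) {
        feature[i] <- "intergenic"
      } else {
        host <- inside[order(abs(a - tss[inside]), ids[inside])[1L]]
        in_exon <- !is.null(exons) && length(exons[[host]]) &&
          any(BiocGenerics::start(exons[[host]]) <= a &
                a <= BiocGenerics::end(exons[[host]]))
        feature[i] <- if (in_exon) "exon" else "intron"
      }
    }
  }
  data.frame(peak_name = nm, chrom = pk_chr, start = start(peaks),
             end = end(peaks), anchor = anchor, feature = feature,
             nearest_gene = nearest_gene, distance_to_tss = dist_tss)
}

#' Genes bound at their promoter
#'
#' A gene is bound when at least one peak annotates as a promoter peak of
#' that gene; the result is a deduplicated, sorted gene-id set. Peaks
#' elsewhere (gene body, 3' end, intergenic) never add a gene.
#'
#' @inheritParams annotate_peaks
#' @return Character vector of bound gene ids.
#' @export
bound_genes <- function(peaks, genes, promoter_dist = 1000) {
  ann <- annotate_peaks(peaks, genes, promoter_dist = promoter_dist)
  sort(unique(ann$nearest_gene[ann$feature == "promoter"]))
}

#' Overlap of a bound-gene set with differential-expression calls
#'
#' Fractions of the bound set that are down-regulated, up-regulated, or
#' neither; the three fractions sum to 1.
#'
#' @param bound Character vector of bound gene ids.
#' @param de_up,de_down Character vectors of up-/down-regulated gene ids,
#'   or the data frames returned by [filter_de()].
#' @return List with `n_bound`, `fraction_down`, `fraction_up`,
#'   `fraction_neither` and the corresponding counts.
#' @export
bound_vs_de <- function(bound, de_up, de_down) {
  if (is.data.frame(de_up)) de_up <- de_up$gene_id
  if (is.data.frame(de_down)) de_down <- de_down$gene_id
  bound <- unique(as.character(bound))
  n <- length(bound)
  if (!n)
    return(list(n_bound = 0L, fraction_down = NA_real_,
                fraction_up = NA_real_, fraction_neither = NA_real_,
                n_down = 0L, n_up = 0L, n_neither = 0L))
  in_down <- bound %in% de_down
  in_up <- bound %in% de_up & !in_down
  neither <- !in_down & !in_up
  list(n_bound = n,
       fraction_down = mean(in_down),
       fraction_up = mean(in_up),
       fraction_neither = mean(neither),
       n_down = sum(in_down), n_up = sum(in_up), n_neither = sum(neither))
}
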