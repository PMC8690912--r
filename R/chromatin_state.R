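#' Histone-mark query windows around gene anchors
#'
#' Builds the strand-oriented windows in which each mark is scored:
#' H3K4me3 within +/- `k4_flank` of the TSS, H3K79me2 within the first
#' `k79_body` bases of the gene body (transcription direction), and
#' H3K27me3 within +/- `k27_flank` of the TSS.
#'
#' @param genes GRanges of gene models.
#' @param k4_flank,k27_flank Symmetric TSS flank widths in bases (defaults
#'   2000 and 5000).
#' @param k79_body Gene-body window length in bases (default 5000).
#' @return Named list of GRanges (`k4`, `k79`, `k27`), one range per gene,
#'   clipped to chromosome ends when lengths are known.
#' @export
mark_windows <- function(genes, k4_flank = 2000, k79_body = 5000,
                         k27_flank = 5000) {
  k4 <- trim(suppressWarnings(
    promoters(genes, upstream = k4_flank, downstream = k4_flank + 1L)))
  k79 <- trim(suppressWarnings(
    promoters(genes, upstream = 0L, downstream = k79_body)))
  k27 <- trim(suppressWarnings(
    promoters(genes, upstream = k27_flank, downstream = k27_flank + 1L)))
  list(k4 = k4, k79 = k79, k27 = k27)
}

#' Is a mark present in its window?
#'
#' A mark is called present for a gene when at least one peak overlaps the
#' gene's query window by one base or more (peak-call presence, not a
#' signal threshold).
#'
#' @param windows GRanges of per-gene query windows (one component of
#'   [mark_windows()]).
#' @param peaks GRanges of peaks for that mark.
#' @return Logical vector, one flag per gene.
#' @export
mark_present <- function(windows, peaks) {
  overlapsAny(windows, peaks, ignore.strand = TRUE)
}

#' Default flag-to-state rule table
#'
#' The standard bivalent-domain definition: a gene is `bivalent` when it
#' carries both H3K4me3 and H3K27me3; `active` when it carries an active
#' mark (H3K4me3 or H3K79me2) without H3K27me3; `silent` otherwise
#' (H3K27me3 only, or no marks).
#'
#' @return Data frame with logical columns k4, k79, k27 covering all 8
#'   combinations and a `state` column.
#' @export
default_rule_table <- function() {
  g <- expand.grid(k4 = c(FALSE, TRUE), k79 = c(FALSE, TRUE),
                   k27 = c(FALSE, TRUE))
  g$state <- ifelse(g$k4 & g$k27, "bivalent",
             ifelse((g$k4 | g$k79) & !g$k27, "active", "silent"))
  g
}

#' Map mark-presence flags to a chromatin state
#'
#' @param k4,k79,k27 Logical vectors (recycled to common length).
#' @param rule_table Data frame covering all 8 flag combinations exactly
#'   once with a `state` column; see [default_rule_table()].
#' @return Factor with levels active/bivalent/silent (plus any extra
#'   labels a custom table introduces).
#' @export
classify_state <- function(k4, k79, k27, rule_table = default_rule_table()) {
  req <- c("k4", "k79", "k27", "state")
  if (!all(req %in% names(rule_table)))
    stop("rule table must have columns k4, k79, k27, state")
  key <- paste(rule_table$k4, rule_table$k79, rule_table$k27)
  if (anyDuplicated(key) || length(key) != 8L)
    stop("rule table must cover all 8 flag combinations exactly once")
  n <- max(length(k4), length(k79), length(k27))
  q <- paste(rep_len(as.logical(k4), n), rep_len(as.logical(k79), n),
             rep_len(as.logical(k27), n))
  lev <- unique(c("active", "bivalent", "silent", rule_table$state))
  factor(rule_table$state[match(q, key)], levels = lev)
}

#' Classify a gene cohort from mark peak sets
#'
#' Scores each mark in its [mark_windows()] window and applies the rule
#' table, yielding one chromatin call per gene.
#'
#' @param genes GRanges of gene models with `gene_id`.
#' @param k4_peaks,k79_peaks,k27_peaks GRanges of peak calls per mark.
#' @param rule_table See [classify_state()].
#' @param ... Window widths passed to [mark_windows()].
#' @return Data frame with columns gene_id, k4, k79, k27, state.
#' @export
classify_genes <- function(genes, k4_peaks, k79_peaks, k27_peaks,
                           rule_table = default_rule_table(), ...) {
  w <- mark_windows(genes, ...)
  k4 <- mark_present(w$k4, k4_peaks)
  k79 <- mark_present(w$k79, k79_peaks)
  k27 <- mark_present(w$k27, k27_peaks)
  data.frame(gene_id = .gene_ids(genes), k4 = k4, k79 = k79, k27 = k27,
             state = classify_state(k4, k79, k27, rule_table))
}

#' Read a differential-expression table
#'
#' Tab-separated table with (at least) gene id, log2 fold change, p-value
#' and adjusted p-value (FDR) columns; column names are mapped via
#' `columns`.
#'
#' @param path TSV path with a header row.
#' @param columns Named character vector mapping standard names
#'   (gene_id, log2fc, p, fdr) to the file's column names.
#' @return Data frame with columns gene_id, log2fc, p, fdr, direction.
#' @export
read_de_table <- function(path,
                          columns = c(gene_id = "gene_id", log2fc = "log2fc",
                                      p = "p", fdr = "fdr")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(columns), names(tab))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(gene_id = as.character(tab[[columns[["gene_id"]]]]),
                    log2fc = as.numeric(tab[[columns[["log2fc"]]]]),
                    p = as.numeric(tab[[columns[["p"]]]]),
                    fdr = as.numeric(tab[[columns[["fdr"]]]]))
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out
}

#' Named differential-expression threshold presets
#'
#' Three published-style cutoff sets: `results_v1` (fold > 1.5, p < 0.05,
#' FDR < 0.1; the package default), `results_v2` (fold > 1.5, FDR < 0.05,
#' p < 0.1) and `methods` (fold > 2, FDR < 0.05, no p cutoff).
#'
#' @return Named list of `c(fold_min, p_max, fdr_max)` vectors.
#' @export
de_presets <- function() {
  list(results_v1 = c(fold_min = 1.5, p_max = 0.05, fdr_max = 0.1),
       results_v2 = c(fold_min = 1.5, p_max = 0.1, fdr_max = 0.05),
       methods = c(fold_min = 2, p_max = 1, fdr_max = 0.05))
}

#' Filter a differential-expression table into up/down gene sets
#'
#' A record passes when its absolute fold change is at least `fold_min`
#' (i.e. `|log2fc| >= log2(fold_min)`), `p <= p_max` and `fdr <= fdr_max`;
#' boundary equality is included. The sign of log2fc assigns direction.
#' Records with missing values are skipped with a message.
#'
#' @param de Data frame with columns gene_id, log2fc, p, fdr (see
#'   [read_de_table()]).
#' @param fold_min Minimum absolute fold change (default 1.5).
#' @param p_max Maximum p-value (default 0.05).
#' @param fdr_max Maximum FDR (default 0.1).
#' @param preset Optional preset name from [de_presets()]; overrides the
#'   three thresholds.
#' @return List with `up` and `down` data frames (disjoint subsets of
#'   `de`).
#' @export
filter_de <- function(de, fold_min = 1.5, p_max = 0.05, fdr_max = 0.1,
                      preset = NULL) {
  if (!is.null(preset)) {
    ps <- de_presets()[[preset]]
    if (is.null(ps)) stop("unknown DE preset: ", preset)
    fold_min <- ps[["fold_min"]]; p_max <- ps[["p_max"]]
    fdr_max <- ps[["fdr_max"]]
  }
  stopifnot(fold_min > 0, p_max > 0, fdr_max > 0)
  bad <- is.na(de$log2fc) | is.na(de$p) | is.na(de$fdr) | is.na(de$gene_id)
  if (any(bad))
    message(sum(bad), " malformed DE record(s) skipped")
  de <- de[!bad, , drop = FALSE]
  pass <- abs(de$log2fc) >= log2(fold_min) & de$p <= p_max &
    de$fdr <= fdr_max
  list(up = de[pass & de$log2fc > 0, , drop = FALSE],
       down = de[pass & de$log2fc < 0, , drop = FALSE])
}

#' Chromatin-state composition of a gene list
#'
#' Percentage of a gene list falling into each chromatin state, given a
#' table of per-gene calls; genes absent from the calls are counted
#' separately, not folded into the percentages.
#'
#' @param gene_ids Character vector of gene ids.
#' @param calls Data frame from [classify_genes()].
#' @return Data frame with columns state, n, percent (percentages over the
#'   called genes, summing to 100); the number of genes without a call is
#'   attached as attribute `n_uncalled`.
#' @export
state_composition <- function(gene_ids, calls) {
  gene_ids <- unique(as.character(gene_ids))
  idx <- match(gene_ids, calls$gene_id)
  uncalled <- sum(is.na(idx))
  st <- calls$state[idx[!is.na(idx)]]
  lev <- levels(factor(calls$state))
  tab <- table(factor(st, levels = lev))
  n_called <- sum(tab)
  out <- data.frame(state = names(tab), n = as.integer(tab),
                    percent = if (n_called > 0)
                      as.numeric(tab) / n_called * 100 else rep(0, length(tab)))
  attr(out, "n_uncalled") <- uncalled
  out
}

#' Overlap summary of 2-3 named gene sets
#'
#' Sizes, pairwise and triple intersections, union size, and the
#' non-overlap percentage of each set (fraction of its members found in no
#' other set) -- the quantities behind a Venn diagram.
#'
#' @param sets Named list of 2 or 3 character vectors (duplicates are
#'   dropped).
#' @return List with `sizes`, `intersections` (named counts), `union_size`
#'   and `non_overlap_percent`.
#' @export
overlap_summary <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L ||
      is.null(names(sets)))
    stop("sets must be a named list of 2 or 3 gene-id vectors")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  sizes <- vapply(sets, length, integer(1))
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  inter <- vapply(pairs, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])), integer(1))
  names(inter) <- vapply(pairs, paste, "", collapse = "&")
  if (length(sets) == 3L) {
    inter <- c(inter, stats::setNames(
      length(Reduce(intersect, sets)), paste(nm, collapse = "&")))
  }
  non_overlap <- vapply(nm, function(a) {
    others <- unlist(sets[setdiff(nm, a)], use.names = FALSE)
    if (!sizes[[a]]) return(NA_real_)
    length(setdiff(sets[[a]], others)) / sizes[[a]] * 100
  }, numeric(1))
  list(sizes = sizes, intersections = inter,
       union_size = length(unique(unlist(sets, use.names = FALSE))),
       non_overlap_percent = non_overlap)
}
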