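#' Simulate a gene annotation on a synthetic chromosome
#'
#' Lays out non-overlapping genes of varying length along one chromosome
#' with intergenic gaps large enough that every gene passes the 4-kb
#' isolation rule and no gene's mark windows reach a neighbour. Strands
#' are drawn at random.
#'
#' @param n_genes Number of genes (default 200).
#' @param gene_length_range Min/max gene length in bases (default
#'   2000-10000).
#' @param gap_range Min/max intergenic gap in bases (default 12000-20000).
#' @param chrom Chromosome name.
#' @param margin Bases kept free at both chromosome ends (default 20000).
#' @param seed Mandatory RNG seed; the layout is reproducible.
#' @return List with `genes` (GRanges with gene_id) and `sizes` (named
#'   chromosome length).
#' @export
simulate_genome <- function(n_genes = 200,
                            gene_length_range = c(2000, 10000),
                            gap_range = c(12000, 20000),
                            chrom = "chrS", margin = 20000, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  lens <- round(stats::runif(n_genes, gene_length_range[1],
                             gene_length_range[2]))
  gaps <- round(stats::runif(n_genes, gap_range[1], gap_range[2]))
  starts <- margin + cumsum(gaps) + c(0, cumsum(lens[-n_genes]))
  ends <- starts + lens - 1
  chromlen <- ends[n_genes] + margin
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- GRanges(chrom, IRanges(starts, ends), strand = strands,
                   gene_id = sprintf("g%04d", seq_len(n_genes)))
  sizes <- chrom_sizes(stats::setNames(chromlen, chrom))
  seqlevels(genes) <- names(sizes)
  seqlengths(genes) <- unname(sizes)
  list(genes = genes, sizes = sizes)
}

#' Planted per-gene simulation parameters
#'
#' Each gene emits reads from a four-component mixture on fragment 5'
#' ends: a promoter-proximal Gaussian just downstream of the TSS, a
#' uniform gene-body plateau, a Gaussian 3'-end peak at the TES, and a
#' uniform chromosome-wide background. Component weights sum to 1 per
#' gene; `expression` is the expected read count (Poisson).
#'
#' @param genes GRanges of gene models.
#' @param pi_promoter,pi_body,pi_terminal,pi_background Mixture weights
#'   (recycled per gene; renormalized to sum to 1). Defaults 0.45 / 0.40 /
#'   0.10 / 0.05 emulate a paused, actively transcribed gene.
#' @param promoter_offset Mean of the promoter component downstream of the
#'   TSS, bases (default 50).
#' @param promoter_sd,terminal_sd Gaussian spreads in bases (defaults 80
#'   and 300).
#' @param expression Expected reads per gene (default 500).
#' @return Data frame (one row per gene) with the planted parameters.
#' @export
sim_truth <- function(genes, pi_promoter = 0.45, pi_body = 0.40,
                      pi_terminal = 0.10, pi_background = 0.05,
                      promoter_offset = 50, promoter_sd = 80,
                      terminal_sd = 300, expression = 500) {
  n <- length(genes)
  w <- cbind(pi_p = rep_len(pi_promoter, n), pi_b = rep_len(pi_body, n),
             pi_t = rep_len(pi_terminal, n),
             pi_bg = rep_len(pi_background, n))
  if (any(w < 0)) stop("mixture weights must be non-negative")
  tot <- rowSums(w)
  if (any(tot <= 0)) stop("mixture weights must not all be zero")
  w <- w / tot
  data.frame(gene_id = .gene_ids(genes), w,
             mu_p = rep_len(promoter_offset, n),
             sigma_p = rep_len(promoter_sd, n),
             sigma_t = rep_len(terminal_sd, n),
             expression = rep_len(expression, n))
}

#' Reweight planted parameters to emulate factor depletion
#'
#' Multiplies the promoter, body and terminal weights and renormalizes all
#' four weights per gene, mimicking the occupancy shift seen upon loss of
#' a pause-release factor (promoter weight up, body weight down) without
#' changing total expression.
#'
#' @param truth Data frame from [sim_truth()].
#' @param promoter_mult,body_mult,terminal_mult,background_mult
#'   Multipliers (defaults 2, 0.5, 1, 1).
#' @return Reweighted truth data frame.
#' @export
apply_depletion <- function(truth, promoter_mult = 2, body_mult = 0.5,
                            terminal_mult = 1, background_mult = 1) {
  stopifnot(promoter_mult >= 0, body_mult >= 0, terminal_mult >= 0,
            background_mult >= 0)
  w <- cbind(truth$pi_p * promoter_mult, truth$pi_b * body_mult,
             truth$pi_t * terminal_mult, truth$pi_bg * background_mult)
  tot <- rowSums(w)
  if (any(tot <= 0)) stop("depletion multipliers zeroed a gene's weights")
  w <- w / tot
  truth$pi_p <- w[, 1]; truth$pi_b <- w[, 2]
  truth$pi_t <- w[, 3]; truth$pi_bg <- w[, 4]
  truth
}

#' Simulate strand-aware ChIP-seq reads with planted structure
#'
#' For each gene, draws `N ~ Poisson(expression)` fragment 5' ends from
#' the gene's mixture: promoter `Normal(TSS + mu_p, sigma_p)` and terminal
#' `Normal(TES, sigma_t)` in transcription-direction coordinates, body
#' `Uniform[TSS + 300, TES]`, background uniform over the chromosome with
#' random strand. Gene-component reads carry the gene's strand; every read
#' is `read_length` long from its 5' end and clipped to the chromosome.
#' Identical seed, truth and genes reproduce the identical read set.
#'
#' @param truth Data frame from [sim_truth()] (row order = gene order).
#' @param genes GRanges of gene models; every gene must be longer than 300
#'   bases (the body component starts 300 bases past the TSS).
#' @param sizes Named chromosome lengths.
#' @param read_length Read length in bases (default 36).
#' @param seed Mandatory RNG seed.
#' @return GRanges of reads (strand set), with a `component` metadata
#'   column naming the generating mixture component.
#' @export
simulate_reads <- function(truth, genes, sizes, read_length = 36, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(nrow(truth) == length(genes))
  if (any(width(genes) <= 300))
    stop("degenerate gene(s) of length <= 300 bp cannot be simulated")
  sizes <- chrom_sizes(sizes)
  set.seed(seed)
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  strs <- as.character(strand(genes))
  chs <- as.character(seqnames(genes))
  dirs <- ifelse(strs == "+", 1, -1)
  pos <- integer(0); chrom <- character(0); str <- character(0)
  comp <- character(0)
  comp_names <- c("promoter", "body", "terminal", "background")
  for (i in seq_along(genes)) {
    n <- stats::rpois(1L, truth$expression[i])
    if (n == 0L) next
    k <- sample.int(4L, n, replace = TRUE,
                    prob = c(truth$pi_p[i], truth$pi_b[i], truth$pi_t[i],
                             truth$pi_bg[i]))
    p <- numeric(n)
    np <- sum(k == 1L); nb <- sum(k == 2L); nt <- sum(k == 3L)
    ng <- sum(k == 4L)
    if (np) p[k == 1L] <- round(tss[i] + dirs[i] *
        stats::rnorm(np, truth$mu_p[i], truth$sigma_p[i]))
    if (nb) p[k == 2L] <- round(tss[i] + dirs[i] *
        stats::runif(nb, 300, width(genes)[i] - 1))
    if (nt) p[k == 3L] <- round(tes[i] + dirs[i] *
        stats::rnorm(nt, 0, truth$sigma_t[i]))
    if (ng) p[k == 4L] <- round(stats::runif(ng, 1, sizes[[chs[i]]]))
    s <- rep(strs[i], n)
    if (ng) s[k == 4L] <- sample(c("+", "-"), ng, replace = TRUE)
    pos <- c(pos, p); chrom <- c(chrom, rep(chs[i], n))
    str <- c(str, s); comp <- c(comp, comp_names[k])
  }
  if (!length(pos))
    return(GRanges(seqlengths = sizes))
  maxlen <- sizes[chrom]
  pos <- pmin(pmax(pos, 1), maxlen)
  st <- ifelse(str == "+", pos, pos - read_length + 1)
  en <- ifelse(str == "+", pos + read_length - 1, pos)
  st <- pmax(st, 1)
  en <- pmin(en, maxlen)
  gr <- GRanges(chrom, IRanges(st, en), strand = str, component = comp)
  seqlevels(gr) <- names(sizes)
  seqlengths(gr) <- unname(sizes)
  sort(gr, ignore.strand = TRUE)
}

#' Simulate histone-mark peak sets for a planted state assignment
#'
#' Emits H3K4me3/H3K79me2/H3K27me3 peak calls consistent with the default
#' rule table: active genes get K4 + K79 peaks, bivalent genes K4 + K27,
#' silent genes K27 only. Peaks are placed well inside each gene's
#' [mark_windows()] windows (with a small seeded positional jitter), so
#' [classify_genes()] on the output recovers the assignment exactly.
#'
#' @param genes GRanges of gene models.
#' @param states Character vector (or factor) of planted states
#'   (active/bivalent/silent), one per gene.
#' @param seed Mandatory RNG seed.
#' @return Named list of GRanges (`k4`, `k79`, `k27`).
#' @export
simulate_marks <- function(genes, states, seed) {
  if (missing(seed)) stop("seed is required")
  states <- as.character(states)
  stopifnot(length(states) == length(genes),
            all(states %in% c("active", "bivalent", "silent")))
  set.seed(seed)
  tss <- gene_tss(genes)
  dirs <- ifelse(as.character(strand(genes)) == "+", 1, -1)
  chs <- as.character(seqnames(genes))
  jitter <- function(n) round(stats::runif(n, -100, 100))
  mk <- function(centers, half, idx) {
    if (!length(idx)) return(GRanges())
    ctr <- centers[idx] + jitter(length(idx))
    GRanges(chs[idx], IRanges(pmax(1, ctr - half), ctr + half),
            name = paste0("pk_", seq_along(idx)), score = 100)
  }
  k4_idx <- which(states %in% c("active", "bivalent"))
  k79_idx <- which(states == "active")
  k27_idx <- which(states %in% c("bivalent", "silent"))
  list(k4 = mk(tss, 300, k4_idx),
       k79 = mk(tss + dirs * 1000, 500, k79_idx),
       k27 = mk(tss, 300, k27_idx))
}

#' Simulate a differential-expression table with planted effects
#'
#' Planted down-/up-regulated genes receive log2 fold changes at (or
#' beyond) the stated fold with near-zero p-values; all other genes are
#' null with `p ~ Uniform(0,1)` and small fold changes (|fold| < 1.35).
#' FDR is Benjamini-Hochberg over the whole table, so [filter_de()] at
#' default thresholds recovers exactly the planted sets.
#'
#' @param genes GRanges (or character vector) of gene ids.
#' @param down_genes,up_genes Character vectors of planted gene ids.
#' @param fold Planted minimum absolute fold change (default 2).
#' @param seed Mandatory RNG seed.
#' @return Data frame with columns gene_id, log2fc, p, fdr, direction.
#' @export
simulate_de <- function(genes, down_genes = character(0),
                        up_genes = character(0), fold = 2, seed) {
  if (missing(seed)) stop("seed is required")
  ids <- if (is.character(genes)) genes else .gene_ids(genes)
  stopifnot(all(down_genes %in% ids), all(up_genes %in% ids),
            !length(intersect(down_genes, up_genes)), fold > 1)
  set.seed(seed)
  n <- length(ids)
  log2fc <- pmin(pmax(stats::rnorm(n, 0, 0.1), -0.4), 0.4)
  p <- stats::runif(n)
  dn <- ids %in% down_genes
  up <- ids %in% up_genes
  eff <- function(m) log2(fold) * (1 + stats::runif(m, 0, 0.5))
  log2fc[dn] <- -eff(sum(dn))
  log2fc[up] <- eff(sum(up))
  p[dn | up] <- stats::runif(sum(dn | up), 1e-10, 1e-8)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = ids, log2fc = log2fc, p = p, fdr = fdr,
             direction = ifelse(log2fc >= 0, "up", "down"))
}

#' Write a DE table as TSV
#'
#' @param de Data frame from [simulate_de()] or [read_de_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
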