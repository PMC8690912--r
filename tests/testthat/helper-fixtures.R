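# Small fixtures built in code.

uniform_track <- function(v, chrom_len = 20000, bin_size = 20,
                          chrom = "chr1") {
  nb <- ceiling(chrom_len / bin_size)
  as_coverage_track(stats::setNames(list(rep(v, nb)), chrom), bin_size,
                    stats::setNames(chrom_len, chrom))
}

random_track <- function(chrom_len = 20000, bin_size = 20, chrom = "chr1",
                         seed = 1) {
  set.seed(seed)
  nb <- ceiling(chrom_len / bin_size)
  as_coverage_track(stats::setNames(list(round(stats::runif(nb, 0, 50), 3)),
                                    chrom),
                    bin_size, stats::setNames(chrom_len, chrom))
}

# A single gene with enough flanking room on a 20 kb chromosome.
one_gene <- function(strand = "+", gs = 6001, ge = 10000, chrom = "chr1") {
  GRanges(chrom, IRanges(gs, ge), strand = strand, gene_id = "gX")
}

random_fragments <- function(n, chrom_len, chrom = "chr1", max_width = 200) {
  s <- sample.int(chrom_len - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GRanges(chrom, IRanges(s, width = w))
}
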