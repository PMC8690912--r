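test_that("uniform occupancy gives TR = 1 and PI3 = 1 on both strands", {
  tr <- uniform_track(2)
  for (s in c("+", "-")) {
    g <- one_gene(s)
    expect_equal(unname(traveling_ratio(tr, g)), 1, tolerance = 1e-12)
    expect_equal(unname(pausing_index_3prime(tr, g)), 1,
                 tolerance = 1e-12)
  }
})

test_that("TR arithmetic: promoter density 10 over empty body gives 1001", {
  nb <- 1000
  vals <- numeric(nb)
  vals[49:65] <- 10  # bases 961-1300 cover window a = [971,1300] of gene below
  track <- as_coverage_track(list(chr1 = vals), 20, c(chr1 = 20000))
  g <- GRanges("chr1", IRanges(1001, 2000), strand = "+", gene_id = "g1")
  expect_equal(unname(traveling_ratio(track, g, eps = 0.01)),
               10.01 / 0.01, tolerance = 1e-9)
})

test_that("PI3 arithmetic: signal confined to the termination window", {
  nb <- 1000
  vals <- numeric(nb)
  vals[101:300] <- 4  # bases 2001-6000; gene ends at 2000, c = [2000,5999]
  track <- as_coverage_track(list(chr1 = vals), 20, c(chr1 = 20000))
  g <- GRanges("chr1", IRanges(1001, 2000), strand = "+", gene_id = "g1")
  d_c <- 4 * 3999 / 4000  # base 2000 carries no signal
  expect_equal(unname(pausing_index_3prime(track, g, eps = 0.01)),
               (d_c + 0.01) / 0.01, tolerance = 1e-9)
})

test_that("TR with eps = 0 is exactly scale invariant on positive tracks", {
  set.seed(41)
  vals <- runif(1000, 0.5, 20)
  t1 <- as_coverage_track(list(chr1 = vals), 20, c(chr1 = 20000))
  t2 <- as_coverage_track(list(chr1 = vals * 7.3), 20, c(chr1 = 20000))
  genes <- c(one_gene("+", 5001, 9000), one_gene("-", 12001, 15000))
  genes$gene_id <- c("gA", "gB")
  expect_equal(traveling_ratio(t1, genes, eps = 0),
               traveling_ratio(t2, genes, eps = 0), tolerance = 1e-12)
  expect_equal(pausing_index_3prime(t1, genes, eps = 0),
               pausing_index_3prime(t2, genes, eps = 0),
               tolerance = 1e-12)
})

test_that("genes too short for a body window are skipped with a message", {
  tr <- uniform_track(1)
  g <- GRanges("chr1", IRanges(5001, 5200), strand = "+", gene_id = "tiny")
  expect_message(out <- traveling_ratio(tr, g), "skipped")
  expect_true(is.na(out[["tiny"]]))
})

test_that("tier assignment reproduces the published partition arithmetic", {
  set.seed(42)
  partition <- function(n) as.integer(table(assign_tiers(
    stats::setNames(runif(n), sprintf("g%05d", seq_len(n))))))
  expect_equal(partition(515), c(155L, 103L, 257L))
  expect_equal(partition(1994), c(599L, 398L, 997L))
  expect_equal(partition(680), c(204L, 136L, 340L))
  # one gene: ceiling(0.3 * 1) = 1 -> high
  expect_equal(as.character(assign_tiers(c(gX = 5))), "high")
})

test_that("tiers are stable under input order and break ties by gene id", {
  set.seed(43)
  sig <- stats::setNames(runif(100), sprintf("g%03d", 1:100))
  t1 <- assign_tiers(sig)
  shuffle <- sample(100)
  t2 <- assign_tiers(sig[shuffle])
  expect_equal(as.character(t2), as.character(t1[shuffle]))
  # all-equal signals: ranking falls back to gene id, so the
  # lexicographically first ids take the high tier
  tied <- stats::setNames(rep(1, 10), sprintf("g%02d", 1:10))
  tt <- assign_tiers(tied)
  expect_equal(as.character(tt[1:3]), rep("high", 3))
  expect_equal(as.character(tt[4:5]), rep("intermediate", 2))
})

test_that("condition comparison matches exact Mann-Whitney enumeration", {
  idc <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_gte(idc$p_value, 0.99)
  expect_equal(idc$direction, "equal")

  sep <- compare_conditions(c(1, 2, 3), c(10, 20, 30))
  orc <- oracle_mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, orc$p, tolerance = 1e-12)
  expect_equal(sep$direction, "b_higher")

  set.seed(44)
  for (rep in 1:10) {
    a <- runif(sample(3:8, 1))
    b <- runif(sample(3:8, 1))
    got <- compare_conditions(a, b)
    want <- oracle_mann_whitney(a, b)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("rank-sum p agrees with a permutation test within Monte-Carlo error", {
  set.seed(45)
  a <- rnorm(20, 0.3)
  b <- rnorm(20)
  got <- compare_conditions(a, b)
  pooled <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- length(a) * length(b) / 2
  u_obs <- u_of(a, b)
  B <- 4000
  hits <- 0
  for (i in seq_len(B)) {
    idx <- sample(40, 20)
    if (abs(u_of(pooled[idx], pooled[-idx]) - mu) >= abs(u_obs - mu))
      hits <- hits + 1
  }
  expect_lt(abs(hits / B - got$p_value), 0.05)
})

test_that("a more promoter-weighted cohort has the higher median TR", {
  genome <- simulate_genome(n_genes = 100, seed = 401)
  paused <- sim_truth(genome$genes, pi_promoter = 0.8, pi_body = 0.1,
                      pi_terminal = 0.05, pi_background = 0.05)
  released <- sim_truth(genome$genes, pi_promoter = 0.2, pi_body = 0.7,
                        pi_terminal = 0.05, pi_background = 0.05)
  tr_of <- function(truth, seed) {
    reads <- simulate_reads(truth, genome$genes, genome$sizes, seed = seed)
    track <- compute_coverage(extend_reads(reads, 150, genome$sizes),
                              genome$sizes, total_reads = length(reads))
    traveling_ratio(track, genome$genes)
  }
  expect_gt(median(tr_of(paused, 402), na.rm = TRUE),
            median(tr_of(released, 403), na.rm = TRUE))
})

test_that("a stronger planted 3' component raises the median pausing index", {
  genome <- simulate_genome(n_genes = 100, seed = 404)
  hi <- sim_truth(genome$genes, pi_terminal = 0.3, pi_body = 0.45)
  lo <- sim_truth(genome$genes, pi_terminal = 0.1, pi_body = 0.65)
  pi_of <- function(truth, seed) {
    reads <- simulate_reads(truth, genome$genes, genome$sizes, seed = seed)
    track <- compute_coverage(extend_reads(reads, 150, genome$sizes),
                              genome$sizes, total_reads = length(reads))
    pausing_index_3prime(track, genome$genes)
  }
  expect_gt(median(pi_of(hi, 405), na.rm = TRUE),
            median(pi_of(lo, 406), na.rm = TRUE))
})

test_that("the per-gene metrics table combines TR, PI3, signal and tier", {
  genome <- simulate_genome(n_genes = 30, seed = 407)
  truth <- sim_truth(genome$genes)
  reads <- simulate_reads(truth, genome$genes, genome$sizes, seed = 408)
  track <- compute_coverage(extend_reads(reads, 150, genome$sizes),
                            genome$sizes, total_reads = length(reads))
  m <- pausing_metrics(track, genome$genes)
  expect_equal(nrow(m), 30)
  expect_true(all(m$tr > 0, na.rm = TRUE))
  expect_true(all(m$pi3 > 0, na.rm = TRUE))
  expect_equal(as.integer(table(m$tier)), c(9L, 6L, 15L))
})
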