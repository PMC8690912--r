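test_that("mark windows anchor on the TSS with the field-standard widths", {
  g <- GRanges("chr1", IRanges(10001, 20000), strand = "+", gene_id = "g1")
  w <- mark_windows(g)
  at_tss <- GRanges("chr1", IRanges(10001, 10001))
  upstream3k <- GRanges("chr1", IRanges(7001, 7001))
  expect_true(mark_present(w$k4, at_tss))
  expect_false(mark_present(w$k4, upstream3k))  # 3 kb > the 2 kb K4 flank
  expect_true(mark_present(w$k27, upstream3k))  # within the 5 kb K27 flank
  # K79 is directional: first 5 kb of the body only
  downstream <- GRanges("chr1", IRanges(14500, 14600))
  upstream <- GRanges("chr1", IRanges(9500, 9600))
  expect_true(mark_present(w$k79, downstream))
  expect_false(mark_present(w$k79, upstream))
})

test_that("mark presence flags match a naive per-gene interval scan", {
  set.seed(51)
  genome <- simulate_genome(n_genes = 30, seed = 52)
  peaks <- GRanges("chrS",
                   IRanges(sample.int(max(end(genome$genes)), 100),
                           width = sample(100:800, 100, TRUE)))
  w <- mark_windows(genome$genes)
  tss <- gene_tss(genome$genes)
  str <- as.character(strand(genome$genes))
  naive_overlap <- function(ws, we) {
    vapply(seq_along(ws), function(i)
      any(pmax(start(peaks), ws[i]) <= pmin(end(peaks), we[i])),
      logical(1))
  }
  expect_equal(mark_present(w$k4, peaks),
               naive_overlap(tss - 2000, tss + 2000))
  expect_equal(mark_present(w$k27, peaks),
               naive_overlap(tss - 5000, tss + 5000))
  k79s <- ifelse(str == "+", tss, tss - 4999)
  expect_equal(mark_present(w$k79, peaks),
               naive_overlap(k79s, k79s + 4999))
})

test_that("the default rule table implements the bivalent-domain definition", {
  expect_equal(as.character(classify_state(TRUE, TRUE, FALSE)), "active")
  expect_equal(as.character(classify_state(TRUE, FALSE, TRUE)), "bivalent")
  expect_equal(as.character(classify_state(FALSE, FALSE, FALSE)), "silent")
  expect_equal(as.character(classify_state(FALSE, TRUE, FALSE)), "active")
  expect_equal(as.character(classify_state(FALSE, FALSE, TRUE)), "silent")
  expect_equal(as.character(classify_state(TRUE, TRUE, TRUE)), "bivalent")
  expect_equal(as.character(classify_state(FALSE, TRUE, TRUE)), "silent")
  expect_equal(as.character(classify_state(TRUE, FALSE, FALSE)), "active")
})

test_that("custom rule tables are validated and change only the labels", {
  bad <- default_rule_table()[1:5, ]
  expect_error(classify_state(TRUE, TRUE, FALSE, rule_table = bad),
               "8 flag combinations")
  # a k79-excluding variant: k79-only genes become silent
  alt <- default_rule_table()
  alt$state[alt$k79 & !alt$k4 & !alt$k27] <- "silent"
  expect_equal(as.character(classify_state(FALSE, TRUE, FALSE,
                                           rule_table = alt)), "silent")
  expect_equal(as.character(classify_state(TRUE, TRUE, FALSE,
                                           rule_table = alt)), "active")
})

test_that("DE filtering applies fold, p and FDR cutoffs with boundary equality", {
  de <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(1, 0.2, -1.5, log2(1.5), -2, 0.9),
    p = c(0.01, 0.001, 0.04, 0.05, 0.2, 0.01),
    fdr = c(0.05, 0.001, 0.09, 0.1, 0.01, 0.5))
  out <- filter_de(de)
  # g1 passes up; g2 fails fold (1.15x); g3 passes down; g4 passes up at
  # exact boundaries; g5 fails p; g6 fails fdr
  expect_equal(out$up$gene_id, c("g1", "g4"))
  expect_equal(out$down$gene_id, "g3")
  expect_equal(intersect(out$up$gene_id, out$down$gene_id), character(0))
})

test_that("malformed DE records are skipped with a message, never returned", {
  de <- data.frame(gene_id = c("a", "b"), log2fc = c(2, NA),
                   p = c(0.001, 0.001), fdr = c(0.01, 0.01))
  expect_message(out <- filter_de(de), "1 malformed")
  expect_equal(out$up$gene_id, "a")
})

test_that("the three published threshold presets are selectable", {
  de <- data.frame(gene_id = c("a", "b"), log2fc = c(0.8, 1.2),
                   p = c(0.04, 0.2), fdr = c(0.08, 0.04))
  # default: fold>1.5, p<=0.05, fdr<=0.1 -> only a
  expect_equal(filter_de(de, preset = "results_v1")$up$gene_id, "a")
  # alternative: fold>1.5, p<=0.1, fdr<=0.05 -> none (a fails fdr, b fails p)
  expect_equal(nrow(filter_de(de, preset = "results_v2")$up), 0L)
  # methods preset: fold>2, fdr<=0.05 -> only b
  expect_equal(filter_de(de, preset = "methods")$up$gene_id, "b")
  expect_error(filter_de(de, preset = "nope"), "unknown")
})

test_that("state composition percentages are exact on small lists", {
  calls <- data.frame(gene_id = paste0("g", 1:4),
                      state = c("active", "active", "active", "silent"))
  all_active <- state_composition(paste0("g", 1:3), calls)
  expect_equal(all_active$percent[all_active$state == "active"], 100)
  mix <- state_composition(paste0("g", 1:4), calls)
  expect_equal(mix$percent[mix$state == "active"], 75)
  expect_equal(mix$percent[mix$state == "silent"], 25)
  expect_equal(sum(mix$percent), 100)
  # unknown genes are counted separately, not silently dropped
  with_unknown <- state_composition(c("g1", "zzz"), calls)
  expect_equal(attr(with_unknown, "n_uncalled"), 1L)
})

test_that("a planted 60/25/15 composition is recovered within 3 points at n=1000", {
  set.seed(53)
  states <- sample(c("active", "bivalent", "silent"), 1000, TRUE,
                   prob = c(0.6, 0.25, 0.15))
  calls <- data.frame(gene_id = sprintf("g%04d", 1:1000), state = states)
  comp <- state_composition(calls$gene_id, calls)
  expect_lt(abs(comp$percent[comp$state == "active"] - 60), 3)
  expect_lt(abs(comp$percent[comp$state == "bivalent"] - 25), 3)
  expect_lt(abs(comp$percent[comp$state == "silent"] - 15), 3)
})

test_that("overlap summaries report Venn counts and non-overlap percentages", {
  same <- overlap_summary(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unname(same$non_overlap_percent), c(0, 0))
  disj <- overlap_summary(list(A = c("x"), B = c("y"), C = c("z")))
  expect_equal(unname(disj$non_overlap_percent), c(100, 100, 100))
  two <- overlap_summary(list(S1 = c("A", "B", "C"), S2 = c("B", "C", "D")))
  expect_equal(unname(two$non_overlap_percent), c(100 / 3, 100 / 3),
               tolerance = 1e-12)
  expect_equal(unname(two$intersections), 2L)
})

test_that("overlap summaries satisfy inclusion-exclusion on random sets", {
  set.seed(54)
  for (rep in 1:10) {
    pool <- sprintf("g%03d", 1:60)
    sets <- list(A = sample(pool, 30), B = sample(pool, 25),
                 C = sample(pool, 20))
    s <- overlap_summary(sets)
    lhs <- s$union_size
    rhs <- sum(s$sizes) - sum(s$intersections[1:3]) + s$intersections[[4]]
    expect_equal(lhs, rhs)
  }
})
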