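test_that("fisher_greater matches the closed-form boundary cases", {
  # a=5,b=0,c=0,d=5: only the observed table or more extreme -> 1/C(10,5)
  r <- fisher_greater(5, 0, 0, 5)
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-12)
  # a=0 -> whole upper tail
  expect_equal(fisher_greater(0, 5, 5, 5)$p, 1)
  # zero margin -> p = 1, odds ratio not applicable
  z <- fisher_greater(0, 0, 3, 4)
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
  # Haldane display correction is finite when a cell is zero
  h <- fisher_greater(5, 0, 2, 5)
  expect_true(is.infinite(h$odds_ratio))
  expect_true(is.finite(h$odds_ratio_display))
})

test_that("fisher_greater equals pmf summation and fisher.test", {
  # exhaustive small grid
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) for (d in 0:5) {
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
      next
    expect_equal(fisher_greater(a, b, cc, d)$p,
                 oracle_hyper_tail(a, b, cc, d), tolerance = 1e-12)
  }
  # random tables with margins up to 30, cross-checked against both the
  # pmf oracle and stats::fisher.test
  set.seed(21)
  for (i in 1:200) {
    t <- sample(0:15, 4, replace = TRUE)
    if ((t[1] + t[2]) == 0 || (t[3] + t[4]) == 0 ||
        (t[1] + t[3]) == 0 || (t[2] + t[4]) == 0) next
    p <- fisher_greater(t[1], t[2], t[3], t[4])$p
    expect_equal(p, oracle_hyper_tail(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(t, 2, byrow = TRUE), alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  # monotone in p and permutation-invariant
  set.seed(5)
  p <- runif(20)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("category enrichment handles planted, null, and edge cases", {
  set.seed(61)
  bg <- paste0("g", 1:1000)
  cats <- setNames(sample(c("A", "B"), 1000, TRUE, prob = c(0.2, 0.8)), bg)
  # planted ~2-fold enrichment of A in the target
  in_a <- names(cats)[cats == "A"]
  target <- c(sample(in_a, 80), sample(setdiff(bg, in_a), 120))
  r <- category_enrichment(target, cats, bg)
  ra <- r[r$term == "A", ]
  expect_gt(ra$odds_ratio, 1)
  expect_lt(ra$q, 0.05)
  # target = background -> OR 1, p 1
  r2 <- category_enrichment(bg, cats, bg)
  expect_true(all(r2$p == 1))
  # category absent from target -> p = 1
  cats3 <- setNames(rep(c("X", "Y"), each = 500), bg)
  r3 <- category_enrichment(names(cats3)[cats3 == "Y"][1:50], cats3, bg)
  expect_equal(r3$p[r3$term == "X"], 1)
  expect_error(category_enrichment("g1", cats, character(0)), "background")
})

test_that("term enrichment finds planted terms and skips empty ones", {
  set.seed(62)
  bg <- paste0("g", 1:400)
  target <- paste0("g", 1:60)
  planted <- c(paste0("g", 1:30), paste0("g", 361:370))  # 50% vs 10%
  tm <- list(planted = planted, all = bg, empty = character(0))
  expect_warning(r <- term_enrichment(target, bg, tm), "empty")
  expect_lt(r$q[r$term == "planted"], 0.05)
  expect_equal(r$p[r$term == "all"], 1)  # term covering everything
})

test_that("null simulations keep the empirical FDR controlled", {
  set.seed(63)
  bg <- paste0("g", 1:200)
  n_rep <- 300
  hits <- 0L; tests <- 0L
  for (i in seq_len(n_rep)) {
    cats <- setNames(sample(LETTERS[1:5], 200, TRUE), bg)
    target <- sample(bg, 50)
    r <- category_enrichment(target, cats, bg)
    hits <- hits + sum(r$q < 0.05)
    tests <- tests + nrow(r)
  }
  expect_lte(hits / tests, 0.05 + 2 * sqrt(0.05 * 0.95 / tests))
})

test_that("preservation verdicts cover all 0..7 significance counts", {
  for (k in 0:7) {
    p <- c(rep(1e-6, k), rep(0.5, 7 - k))
    v <- preservation_classify(p, alpha = 0.05, n_comparisons = 7)
    expect_equal(v$n_significant, k)
    expect_equal(v$verdict,
                 if (k == 7) "strong" else if (k >= 1) "moderate_weak"
                 else "none")
  }
  # Bonferroni boundary: raw p below alpha but not after adjustment
  v2 <- preservation_classify(rep(0.02, 7), alpha = 0.05, n_comparisons = 7)
  expect_equal(v2$verdict, "none")
  expect_error(preservation_classify(rep(0.01, 6)), "7")
})

test_that("promoter extraction picks the transcript and window correctly", {
  # (3 exons, 2 kb) vs (5 exons, 1 kb): the 5-exon transcript wins
  mk_tx <- function(id, starts, widths) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, width = widths), strand = "+",
    transcript_id = id, gene_id = "g")
  tx3 <- mk_tx("t3", c(20000, 21000, 22000), c(700, 700, 600))
  tx5 <- mk_tx("t5", c(10001, 10401, 10801, 11201, 11601), rep(200, 5))
  p <- extract_promoter(c(tx3, tx5), 1000L, 500L)
  # 0-based TSS 10000 -> promoter [9000, 10500) -> 1-based [9001, 10500]
  expect_equal(start(p), 9001L)
  expect_equal(end(p), 10500L)
  # minus-strand mirror: 0-based TSS 10000 -> [9500, 11000)
  txm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 10001),
                                strand = "-", transcript_id = "tm",
                                gene_id = "g")
  pm <- extract_promoter(txm, 1000L, 500L)
  expect_equal(start(pm), 9501L)
  expect_equal(end(pm), 11000L)
  # clipping at the chromosome edge
  tx0 <- mk_tx("t0", 200, 100)
  p0 <- extract_promoter(tx0, 1000L, 500L)
  expect_equal(start(p0), 1L)
})

test_that("TF promoter analysis counts distinct TFs and finds planted TFs", {
  set.seed(64)
  n <- 400
  chrom_sizes <- c(chr1 = 5000000L)
  proms <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(10000, by = 10000, length.out = n),
                             width = 1500), strand = "+",
    gene_id = paste0("g", 1:n))
  # TF "planted" binds half the promoters; TFs bgA/bgB are background-only
  peak_rows <- list()
  sel <- sample(n, n / 2)
  ctr <- (start(proms) + end(proms))[sel] %/% 2
  peak_rows$planted <- data.frame(start = ctr - 50, tf = "planted")
  for (tf in c("bgA", "bgB")) {
    peak_rows[[tf]] <- data.frame(
      start = sample.int(4900000L, 300), tf = tf)
  }
  pk <- do.call(rbind, peak_rows)
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(pk$start, width = 100),
                                  name = pk$tf)
  # a promoter overlapped by peaks of TFs {A, A, B} counts 2 distinct
  two <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rep(start(proms)[sel[1]], 3), width = 100),
    name = c("bgA", "bgA", "bgB"))
  r0 <- tf_promoter_analysis(proms[sel[1]], list(g = mcols(proms)$gene_id[sel[1]]),
                             two, chrom_sizes, seed = 2)
  expect_equal(r0$counts$n_tfs, 2L)
  r <- tf_promoter_analysis(proms, list(all = mcols(proms)$gene_id), peaks,
                            chrom_sizes, seed = 3)
  enr <- r$tf_enrichment
  expect_true(enr$enriched[enr$tf == "planted"])
  expect_false(any(enr$enriched[enr$tf %in% c("bgA", "bgB")]))
  expect_lt(r$group_tests$p_wilcox, 0.05)
  # no peaks anywhere -> all counts zero, rank-sum p = 1
  r_none <- tf_promoter_analysis(proms, list(all = mcols(proms)$gene_id),
                                 peaks[0], chrom_sizes, seed = 4)
  expect_true(all(r_none$counts$n_tfs == 0L))
  expect_equal(r_none$group_tests$p_wilcox, 1)
})

test_that("closest-gene report applies the 100 kb rule and class tables", {
  lnc <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 500000, 800000), width = 500),
    gene_id = c("l1", "l2", "l3"))
  groups <- c(l1 = "300", l2 = "300", l3 = "human_specific")
  subj <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1200, 700000), width = 100),
    gene_id = c("s_overlap", "s_far"))
  cls <- c(s_overlap = "homeobox", s_far = "znf")
  r <- closest_gene_report(lnc, groups, subj, cls)
  # l1 overlaps -> distance 0; l2's nearest is ~200 kb away -> excluded
  expect_equal(r$nearest$distance[r$nearest$lncrna_id == "l1"], 0L)
  expect_false("l2" %in% r$nearest$lncrna_id)
  expect_true("l3" %in% r$nearest$lncrna_id)  # ~99.9 kb away
  expect_true(!is.null(r$enrichment))
})
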