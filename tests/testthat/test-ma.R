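test_that("combine_transfers prioritizes the lift over sequence mapping", {
  lifted <- GenomicRanges::GRanges("chrT", IRanges::IRanges(10, 20))
  seqm <- GenomicRanges::GRanges("chrT", IRanges::IRanges(100, 200))
  expect_equal(start(combine_transfers(list(lifted = lifted), seqm)), 10)
  expect_equal(start(combine_transfers(list(lifted = NULL), seqm)), 100)
  expect_null(combine_transfers(list(lifted = NULL), NULL))
})

test_that("reciprocal_filter keeps only pairs present in both directions", {
  fwd <- data.frame(query_id = c("A", "B", "C"),
                    target_id = c("a", "b", "c"))
  rev <- data.frame(query_id = c("A", "B"), target_id = c("a", "x"))
  r <- reciprocal_filter(fwd, rev)
  expect_equal(r$query_id, "A")
  # empty reverse set -> empty output
  expect_equal(nrow(reciprocal_filter(fwd, fwd[0, ])), 0L)
  # symmetry under swapping directions
  swap <- function(p) data.frame(query_id = p$target_id,
                                 target_id = p$query_id)
  r2 <- reciprocal_filter(swap(rev), swap(fwd))
  expect_equal(nrow(r2), nrow(r))
  expect_equal(swap(r2)$query_id, r$query_id)
})

test_that("merge_passes keeps the older label", {
  m <- c(A = "25", B = "300", C = NA, D = "90")
  r <- c(A = "90", B = "25", C = "25", D = NA)
  out <- merge_passes(m, r)
  expect_equal(unname(out[c("A", "B", "C", "D")]),
               c("90", "300", "25", "90"))
})

test_that("oldest-wins merging is associative, commutative, idempotent", {
  set.seed(3)
  labs <- c(ma_levels(), NA)
  for (i in 1:25) {
    a <- setNames(sample(labs, 6, TRUE), letters[1:6])
    b <- setNames(sample(labs, 6, TRUE), letters[1:6])
    cc <- setNames(sample(labs, 6, TRUE), letters[1:6])
    expect_identical(merge_passes(a, b), merge_passes(b, a))
    expect_identical(merge_passes(merge_passes(a, b), cc),
                     merge_passes(a, merge_passes(b, cc)))
    expect_identical(merge_passes(a, a), a)
  }
})

test_that("merge_public retains the oldest label and records provenance", {
  ours <- c(l1 = "25", l2 = "300", l3 = NA, l4 = "90")
  public <- c(l1 = "90", l2 = "25", l3 = "apes", l4 = "90")
  r <- merge_public(ours, public)
  expect_equal(r$label, c("90", "300", "apes", "90"))
  expect_equal(r$provenance, c("public_db", "pipeline", "public_db",
                               "merged"))
  expect_error(merge_public(ours, c(l1 = "ancient")), "unknown")
})

test_that("assign_ma implements the per-species age and uncertainty rules", {
  depths <- c(T25 = 25, T90 = 90, T300 = 300)
  ev <- function(id, sp, recip, nonrecip = FALSE, pass = "te_masked") {
    data.frame(lncrna_id = id, species = sp, pass = pass,
               forward_hit = ifelse(recip | nonrecip, "x", NA),
               reciprocal = recip, nonreciprocal = nonrecip)
  }
  # reciprocal hit in the deepest species only -> 300
  e <- rbind(ev("L", "T300", TRUE), ev("L", "T25", FALSE),
             ev("L", "T90", FALSE))
  expect_equal(assign_ma(e, depths)$label, "300")
  # no hits at all, no public record -> query-specific
  e2 <- rbind(ev("L", "T300", FALSE), ev("L", "T25", FALSE),
              ev("L", "T90", FALSE))
  expect_equal(assign_ma(e2, depths)$label, "human_specific")
  # forward-only hit in one species, no public record -> uncertain
  e3 <- rbind(ev("L", "T90", FALSE, nonrecip = TRUE),
              ev("L", "T25", FALSE), ev("L", "T300", FALSE))
  expect_equal(assign_ma(e3, depths)$label, "uncertain")
  # a public record rescues a nonreciprocal case (never uncertain with
  # public or reciprocal evidence)
  expect_equal(assign_ma(e3, depths, public = c(L = "apes"))$label, "apes")
  # public overrides upward but never downward
  e4 <- rbind(ev("L", "T90", TRUE), ev("L", "T25", TRUE),
              ev("L", "T300", FALSE))
  expect_equal(assign_ma(e4, depths, public = c(L = "300"))$label, "300")
  expect_equal(assign_ma(e4, depths, public = c(L = "25"))$label, "90")
  # TE-retained pass can only raise the label
  e5 <- rbind(ev("L", "T25", TRUE),
              ev("L", "T90", TRUE, pass = "te_retained"),
              ev("L", "T300", FALSE))
  expect_equal(assign_ma(e5, depths)$label, "90")
})

test_that("match_target_lncrna enforces strand and shared-flank clauses", {
  transfer <- GenomicRanges::GRanges("chrT", IRanges::IRanges(100, 200),
                                     strand = "+")
  targets <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(150, 400), c(260, 500)),
    strand = c("+", "-"), gene_id = c("tl1", "tl2"))
  qf <- data.frame(left_id = "qpc1", left_strand = "+",
                   right_id = "qpc2", right_strand = "-")
  tf <- data.frame(left_id = c("tpc1", "zzz"), left_strand = c("+", "+"),
                   right_id = c("tpc2", "tpc2"),
                   right_strand = c("-", "-"))
  ortho <- c(qpc1 = "tpc1", qpc2 = "tpc2")
  expect_equal(match_target_lncrna(transfer, qf, targets, tf, ortho), "tl1")
  # opposite strand -> no match
  t2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(150, 260),
                               strand = "-", gene_id = "tl1")
  expect_true(is.na(match_target_lncrna(transfer, qf, t2, tf[1, ], ortho)))
  # no shared flanking ortholog -> no match
  tf_bad <- data.frame(left_id = "other", left_strand = "+",
                       right_id = "other2", right_strand = "-")
  expect_true(is.na(match_target_lncrna(transfer, qf, targets[1], tf_bad,
                                        ortho)))
  # flank strand must agree too
  tf_strand <- data.frame(left_id = "tpc1", left_strand = "-",
                          right_id = "zzz", right_strand = "-")
  expect_true(is.na(match_target_lncrna(transfer, qf, targets[1],
                                        tf_strand, ortho)))
  # tie broken by largest overlap
  t3 <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(150, 180), c(260, 200)),
    strand = "+", gene_id = c("big", "small"))
  tf3 <- tf[c(1, 1), ]
  expect_equal(match_target_lncrna(transfer, qf, t3, tf3, ortho), "big")
})

test_that("flanking_coding_genes finds nearest flanks within the window", {
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000),
                                 gene_id = "l1")
  coding <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 3000, 8000, 20000),
                             c(1500, 3500, 8500, 20500)),
    strand = c("+", "-", "+", "-"),
    gene_id = c("far_left", "near_left", "near_right", "far_right"))
  f <- flanking_coding_genes(loci, coding, window = 500000L)
  expect_equal(f$left_id, "near_left")
  expect_equal(f$left_strand, "-")
  expect_equal(f$right_id, "near_right")
  # a tight window removes flanks beyond it (left at 1.5 kb, right at 2 kb)
  f2 <- flanking_coding_genes(loci, coding, window = 1800L)
  expect_equal(f2$left_id, "near_left")
  expect_true(is.na(f2$right_id))
})

test_that("zero-noise bundle recovers every planted age", {
  b <- default_bundle()
  res <- annotate_ages(b)
  asg <- res$assignments
  expect_equal(mean(asg$label == b$truth$true_age[asg$lncrna_id]), 1)
  # with reciprocal evidence everywhere, nothing is uncertain
  expect_false(any(asg$label == "uncertain"))
})

test_that("public synteny annotations can only raise pipeline labels", {
  b <- default_bundle()
  hs <- names(b$truth$true_age)[b$truth$true_age == "human_specific"][1]
  old <- names(b$truth$true_age)[b$truth$true_age == "300"][1]
  pub <- setNames(c("apes", "25"), c(hs, old))
  res <- annotate_ages(b, public = pub)
  asg <- res$assignments
  expect_equal(asg$label[asg$lncrna_id == hs], "apes")
  expect_equal(asg$provenance[asg$lncrna_id == hs], "public_db")
  expect_equal(asg$label[asg$lncrna_id == old], "300")  # not demoted
})

test_that("positional classification follows the stated precedence", {
  coding_ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 3000), c(1500, 3500)), strand = "+",
    gene_id = "pc1")
  coding_span <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3500),
                                        strand = "+", gene_id = "pc1")
  mk <- function(s, e, str) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(s, e), strand = str)
  expect_equal(classify_positional_type(mk(1200, 1300, "-"), coding_ex,
                                        coding_span), "antisense")
  expect_equal(classify_positional_type(mk(1200, 1300, "+"), coding_ex,
                                        coding_span), "overlapping")
  expect_equal(classify_positional_type(mk(2000, 2500, "+"), coding_ex,
                                        coding_span), "intronic")
  expect_equal(classify_positional_type(mk(4000, 4500, "+"), coding_ex,
                                        coding_span, 5000L),
               "intergenic_proximal")
  expect_equal(classify_positional_type(mk(300000, 300500, "+"), coding_ex,
                                        coding_span, 5000L),
               "intergenic_distal")
})
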