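test_that("TPM matches the worked example and symmetry cases", {
  # q = (10, 30), l = (1, 2) kb -> rates (10, 15) -> (400000, 600000)
  tpm <- compute_tpm(cbind(s1 = c(10, 30)), c(1, 2))
  expect_equal(unname(tpm[, 1]), c(400000, 600000))
  # equal counts and lengths split evenly
  tpm2 <- compute_tpm(cbind(s = c(5, 5)), c(2, 2))
  expect_equal(unname(tpm2[, 1]), c(5e5, 5e5))
  # one gene takes the whole million
  expect_equal(unname(compute_tpm(cbind(s = 7), 1.5)[, 1]), 1e6)
  expect_error(compute_tpm(cbind(s = c(0, 0)), c(1, 1)), "denominator")
})

test_that("TPM columns sum to 1e6 and are scale-invariant", {
  set.seed(15)
  counts <- matrix(rpois(200, 50), nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  l <- runif(20, 0.2, 10)
  tpm <- compute_tpm(counts, l)
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e6 * 1e-6))
  tpm_scaled <- compute_tpm(counts * 3, l)
  expect_equal(tpm, tpm_scaled)
})

test_that("cortical filter applies the all-samples-per-pair OR DE rule", {
  meta <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                     window = c("W1", "W1", "W2", "W2"),
                     region = "FC")
  tpm <- rbind(
    edge = c(0.5, 0.5, 0.1, 0.1),   # exactly at threshold in pair W1
    low = c(0.4, 0.4, 0.4, 0.4),    # everywhere below
    onep = c(9.0, 0.1, 0.1, 0.1))   # high in only one sample of the pair
  colnames(tpm) <- meta$sample
  expect_equal(cortical_filter(tpm, meta), "edge")
  # strict reading excludes the boundary case
  expect_equal(length(cortical_filter(tpm, meta, strict = TRUE)), 0L)
  # DE membership rescues a lowly expressed gene
  de <- list(cl1 = data.frame(gene_id = "low"))
  expect_setequal(cortical_filter(tpm, meta, de), c("edge", "low"))
})

test_that("exon classes are strand-aware and introns complement exons", {
  ex <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 201, 501, 1001, 1301),
                             c(100, 300, 600, 1100, 1400)),
    strand = c(rep("+", 3), "-", "-"),
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    gene_id = c("g1", "g1", "g1", "g2", "g2"))
  st <- exon_intron_stats(ex)
  t1 <- st$exons[st$exons$transcript_id == "t1", ]
  expect_equal(t1$class, c("first", "internal", "last"))
  # minus strand: rightmost exon is the first
  t2 <- st$exons[st$exons$transcript_id == "t2", ]
  expect_equal(t2$class, c("last", "first"))
  # intron widths fill the span
  tx <- st$transcripts
  for (id in tx$transcript_id) {
    iw <- sum(st$introns$width[st$introns$transcript_id == id])
    expect_equal(tx$span[tx$transcript_id == id],
                 tx$tx_length[tx$transcript_id == id] + iw)
  }
  # single-exon transcripts belong to no positional class
  single <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50),
                                   strand = "+", transcript_id = "s1",
                                   gene_id = "g3")
  st2 <- exon_intron_stats(single)
  expect_equal(st2$transcripts$n_exons, 1L)
  expect_equal(st2$exons$class, "single")
})

test_that("TE content applies the 10 bp rule and the printed ratios", {
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                 gene_id = "g1")
  # one TE overlapping 250 bp of a 1 kb gene -> fraction 0.25
  te <- GenomicRanges::GRanges("chr1", IRanges::IRanges(751, 1100),
                               name = "L1", te_class = "LINE")
  r <- te_content(gene, te)
  expect_equal(r$genes$gene_body_te_fraction, 0.25)
  expect_true(r$genes$has_te)
  # full-length insertion: 300 bp TE entirely inside -> body fraction 1
  te2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400),
                                name = "Alu", te_class = "SINE")
  r2 <- te_content(gene, te2)
  expect_equal(r2$insertions$te_body_fraction, 1)
  # a 9 bp overlap leaves no record
  te3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(992, 1100),
                                name = "Alu", te_class = "SINE")
  r3 <- te_content(gene, te3)
  expect_equal(nrow(r3$insertions), 0L)
  expect_false(r3$genes$has_te)
  # non-whitelisted classes are dropped
  te4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
                                name = "x", te_class = "Simple_repeat")
  expect_false(te_content(gene, te4)$genes$has_te)
  # fraction is capped at 1 and monotone as TEs are added
  r5a <- te_content(gene, te2)
  r5b <- te_content(gene, c(te2, te))
  expect_gte(r5b$genes$gene_body_te_fraction,
             r5a$genes$gene_body_te_fraction)
  expect_lte(r5b$genes$gene_body_te_fraction, 1)
})

test_that("CDS TE flag requires strictly more than half, same strand", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                strand = "+", cds_id = "c1")
  te_half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
                                    strand = "+")
  te_51 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 510),
                                  strand = "+")
  te_anti <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 800),
                                    strand = "-")
  expect_false(cds_te_flag(cds, te_half)[["c1"]])   # exactly 50%
  expect_true(cds_te_flag(cds, te_51)[["c1"]])      # 51%
  expect_false(cds_te_flag(cds, te_anti)[["c1"]])   # wrong strand
  expect_false(cds_te_flag(cds, te_half[0])[["c1"]])
})

test_that("expression matching reproduces the worked example", {
  cov <- c(r1 = 1.0, r2 = 2.0, o1 = 0.9, o2 = 5.0, o3 = 2.1)
  m <- match_expression(list(ref = c("r1", "r2"),
                             other = c("o1", "o2", "o3")), cov, "ref")
  expect_setequal(m$other, c("o1", "o3"))
  expect_equal(length(m$other), 2L)
  # identical distributions give zero total cost
  cov2 <- c(a1 = 1, a2 = 2, b1 = 1, b2 = 2)
  m2 <- match_expression(list(A = c("a1", "a2"), B = c("b1", "b2")), cov2,
                         "A")
  expect_equal(sum(abs(cov2[m2$A] - cov2[m2$B])), 0)
  expect_error(match_expression(list(A = c("a1", "a2"), B = "b1"), cov2,
                                "A"), "smaller")
})

test_that("expression matching equals brute-force optimal assignment", {
  set.seed(88)
  for (rep in 1:100) {
    n <- sample(2:5, 1)
    m <- n + sample(0:3, 1)
    ref <- round(runif(n, 0, 10), 2)
    cand <- round(runif(m, 0, 10), 2)
    names(ref) <- paste0("r", seq_len(n))
    names(cand) <- paste0("c", seq_len(m))
    cov <- c(ref, cand)
    res <- match_expression(list(R = names(ref), C = names(cand)), cov, "R")
    got_cost <- sum(abs(cov[res$R] - cov[res$C]))
    expect_equal(got_cost, oracle_min_assignment(ref, cand),
                 tolerance = 1e-9)
  }
})

test_that("specificity counting bins cluster-marker multiplicity", {
  de <- lapply(1:7, function(i) data.frame(gene_id = c("always",
                                                       if (i == 1) "once")))
  names(de) <- paste0("cl", 1:7)
  r <- specificity_counts(de)
  expect_equal(unname(r$counts[c("always", "once")]), c(7L, 1L))
  expect_equal(as.character(r$bins[["always"]]), "6+")
  expect_equal(as.character(r$bins[["once"]]), "1")
  # genes absent from every table are excluded
  expect_false("ghost" %in% names(r$counts))
  # planted specificity in the synthetic DE tables is recovered exactly
  b <- default_bundle()
  rs <- specificity_counts(b$de_clusters)
  truth <- b$truth$gene_specificity[b$truth$gene_specificity > 0]
  expect_equal(rs$counts[names(truth)], truth)
})
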