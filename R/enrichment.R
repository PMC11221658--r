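# Enrichment statistics: one-sided hypergeometric tests with FDR control,
# generic term/category enrichment, promoter TF analyses against a
# shuffled-region null, and the module-preservation verdict rule.

#' One-sided (greater) Fisher hypergeometric test on a 2x2 table
#'
#' `p = P(X >= a)` for the upper hypergeometric tail with all margins
#' fixed; the odds ratio is the sample cross-product ratio `(a d)/(b c)`
#' (not the conditional MLE). A zero margin gives `p = 1` and an undefined
#' (`NA`) odds ratio. `odds_ratio_display` applies a Haldane 0.5 correction
#' when any cell is zero, for finite heatmap values; p-values are never
#' corrected this way.
#'
#' @param a,b,c,d Non-negative integer cells: in-set & in-category,
#'   in-set & out, out & in-category, out & out.
#' @return List with `odds_ratio`, `odds_ratio_display`, `p`.
#' @examples
#' fisher_greater(5, 0, 0, 5)$p  # 1 / choose(10, 5)
#' @export
fisher_greater <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    disp <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    return(list(odds_ratio = NA_real_, odds_ratio_display = disp, p = 1))
  }
  p <- phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
  or <- (a * d) / (b * c)  # Inf when b*c == 0 with a*d > 0
  disp <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else or
  list(odds_ratio = or, odds_ratio_display = disp, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_i = min_{j >= rank(i)} (m / j) p_(j)`, capped at
#' 1; a thin wrapper over [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Category enrichment of a gene set over a background
#'
#' One 2x2 table per category (set membership x category membership over
#' the background), one-sided hypergeometric p-values and BH q-values
#' across categories. Used identically for cell-type, compartment,
#' TE-family and disease-DE analyses.
#'
#' @param target_set Character vector of gene ids (subset of `background`).
#' @param categories Named character vector: gene id to category label
#'   (genes missing from it count as no category).
#' @param background Character vector of all considered gene ids.
#' @return `data.frame`: `term`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `odds_ratio_display`, `p`, `q`.
#' @export
category_enrichment <- function(target_set, categories, background) {
  if (!length(background)) stop("empty background")
  stopifnot(all(target_set %in% background))
  target_set <- unique(target_set)
  background <- unique(background)
  cat_of <- categories[match(background, names(categories))]
  in_set <- background %in% target_set
  terms <- sort(unique(cat_of[!is.na(cat_of)]))
  rows <- lapply(terms, function(tm) {
    in_cat <- !is.na(cat_of) & cat_of == tm
    a <- sum(in_set & in_cat); b <- sum(in_set & !in_cat)
    cc <- sum(!in_set & in_cat); dd <- sum(!in_set & !in_cat)
    f <- fisher_greater(a, b, cc, dd)
    data.frame(term = tm, a = a, b = b, c = cc, d = dd,
               odds_ratio = f$odds_ratio,
               odds_ratio_display = f$odds_ratio_display, p = f$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Generic term enrichment
#'
#' One-sided hypergeometric + BH per term of an arbitrary gene-to-terms
#' map (the role GO plays in closest-gene analyses). Terms with no member
#' in the background are skipped with a warning.
#'
#' @param gene_set Character vector of gene ids (subset of `background`).
#' @param background Character vector of all gene ids.
#' @param term_map Named list: term to character vector of member genes.
#' @return `data.frame` as in [category_enrichment()].
#' @export
term_enrichment <- function(gene_set, background, term_map) {
  if (!length(background)) stop("empty background")
  stopifnot(all(gene_set %in% background))
  gene_set <- unique(gene_set); background <- unique(background)
  rows <- list()
  for (tm in names(term_map)) {
    members <- intersect(term_map[[tm]], background)
    if (!length(members)) {
      warning("term '", tm, "' has no members in the background; skipped")
      next
    }
    a <- sum(gene_set %in% members)
    b <- length(gene_set) - a
    cc <- length(members) - a
    dd <- length(background) - length(gene_set) - cc
    f <- fisher_greater(a, b, cc, dd)
    rows[[tm]] <- data.frame(term = tm, a = a, b = b, c = cc, d = dd,
                             odds_ratio = f$odds_ratio,
                             odds_ratio_display = f$odds_ratio_display,
                             p = f$p)
  }
  if (!length(rows)) {
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      odds_ratio_display = numeric(0), p = numeric(0),
                      q = numeric(0)))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_fdr(out$p)
  out
}

#' Module preservation verdict from seven test statistics
#'
#' Strong evidence when all seven Bonferroni-adjusted p-values fall below
#' `alpha`; moderate/weak when between one and six do; none when none do.
#'
#' @param pvalues Exactly seven raw p-values.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param n_comparisons Bonferroni multiplier (default 7).
#' @return List with `n_significant` and `verdict` in
#'   `{strong, moderate_weak, none}`.
#' @export
preservation_classify <- function(pvalues, alpha = 0.05, n_comparisons = 7L) {
  if (length(pvalues) != 7L) stop("exactly 7 preservation p-values required")
  adj <- pmin(1, pvalues * n_comparisons)
  n_sig <- sum(adj < alpha)
  verdict <- if (n_sig == 7L) "strong" else if (n_sig >= 1L) "moderate_weak"
             else "none"
  list(n_significant = n_sig, verdict = verdict)
}

# Transcript chosen to represent a gene's promoter: highest exon count,
# then longest (summed exon length), then lexicographically smallest id.
.promoter_transcript <- function(exons_of_gene) {
  by_tx <- split(seq_along(exons_of_gene),
                 mcols(exons_of_gene)$transcript_id)
  n_ex <- vapply(by_tx, length, integer(1))
  len <- vapply(by_tx, function(i) sum(width(exons_of_gene)[i]), numeric(1))
  ids <- names(by_tx)
  ids[order(-n_ex, -len, ids)][1L]
}

#' Extract the promoter of one gene
#'
#' The representative transcript maximizes exon count, then transcript
#' length, then smallest id. The promoter spans `upstream_bp` before and
#' `downstream_bp` after the TSS, strand-aware, clipped to the chromosome.
#'
#' @param transcripts `GRanges` of the gene's exons with `transcript_id`.
#' @param upstream_bp,downstream_bp Window around the TSS (defaults 1000
#'   and 500).
#' @param chrom_sizes Optional named vector for clipping.
#' @return `GRanges` of length 1.
#' @export
extract_promoter <- function(transcripts, upstream_bp = 1000L,
                             downstream_bp = 500L, chrom_sizes = NULL) {
  stopifnot(is(transcripts, "GRanges"), length(transcripts) >= 1L)
  tx <- .promoter_transcript(transcripts)
  ex <- transcripts[mcols(transcripts)$transcript_id == tx]
  minus <- as.character(strand(ex))[1L] == "-"
  if (minus) {
    tss <- max(end(ex))
    s <- tss - downstream_bp; e <- tss + upstream_bp - 1L
  } else {
    tss <- min(start(ex))
    s <- tss - upstream_bp; e <- tss + downstream_bp - 1L
  }
  chrom <- as.character(seqnames(ex))[1L]
  s <- max(1L, s)
  if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
    e <- min(e, chrom_sizes[[chrom]])
  }
  gr <- GRanges(chrom, IRanges(s, e), strand = if (minus) "-" else "+")
  if ("gene_id" %in% names(mcols(transcripts))) {
    mcols(gr)$gene_id <- mcols(transcripts)$gene_id[1L]
  }
  gr
}

#' Extract promoters for every gene of an annotation
#'
#' @param exons `GRanges` of exons with `transcript_id` and `gene_id`.
#' @inheritParams extract_promoter
#' @return `GRanges`, one promoter per gene, with `gene_id`.
#' @export
extract_promoters <- function(exons, upstream_bp = 1000L,
                              downstream_bp = 500L, chrom_sizes = NULL) {
  by_gene <- split(exons, mcols(exons)$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    p <- extract_promoter(by_gene[[g]], upstream_bp, downstream_bp,
                          chrom_sizes)
    data.frame(chrom = as.character(seqnames(p)), start = start(p),
               end = end(p), strand = as.character(strand(p)))
  })
  df <- do.call(rbind, rows)
  GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
          gene_id = names(by_gene))
}

# Distinct TFs with >= 1 bp peak overlap per region.
.distinct_tf_counts <- function(regions, tf_peaks) {
  hits <- findOverlaps(regions, tf_peaks, ignore.strand = TRUE)
  tf <- as.character(mcols(tf_peaks)$name)[subjectHits(hits)]
  counts <- integer(length(regions))
  if (length(hits)) {
    u <- unique(data.frame(r = queryHits(hits), tf = tf))
    tb <- table(u$r)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  counts
}

#' Promoter TF binding analysis against a random-region null
#'
#' Computes the distinct-TF count of every promoter and of an equal number
#' of shuffled random regions, compares each gene group to the random
#' regions with a one-sided (greater) rank-sum test, and tests each TF for
#' enrichment in each group's promoters versus the random regions with
#' one-sided hypergeometric tests, BH-adjusted within group (enriched when
#' `q < 0.05`).
#'
#' @param promoters `GRanges` with `gene_id` metadata.
#' @param groups Named list: group name to gene ids.
#' @param tf_peaks `GRanges` of TF peaks with a `name` column.
#' @param chrom_sizes Named chromosome sizes (for the shuffle null).
#' @param seed Seed for the shuffle.
#' @return List with `counts` (`data.frame`: `gene_id`, `group`, `n_tfs`),
#'   `random_counts`, `group_tests` (`group`, `p_wilcox`), and
#'   `tf_enrichment` (`group`, `tf`, 2x2 cells, `odds_ratio`, `p`, `q`,
#'   `enriched`).
#' @export
tf_promoter_analysis <- function(promoters, groups, tf_peaks, chrom_sizes,
                                 seed = 1L) {
  stopifnot(is(promoters, "GRanges"), "name" %in% names(mcols(tf_peaks)))
  random_regions <- shuffle_intervals(promoters, chrom_sizes, seed = seed)
  pc <- .distinct_tf_counts(promoters, tf_peaks)
  rc <- .distinct_tf_counts(random_regions, tf_peaks)
  gid <- mcols(promoters)$gene_id
  tfs <- sort(unique(as.character(mcols(tf_peaks)$name)))
  prom_tf <- intersect_intervals(promoters, tf_peaks)
  prom_tf$tf <- as.character(mcols(tf_peaks)$name)[prom_tf$b_idx]
  rand_tf <- intersect_intervals(random_regions, tf_peaks)
  rand_tf$tf <- as.character(mcols(tf_peaks)$name)[rand_tf$b_idx]
  n_rand <- length(random_regions)
  counts_rows <- list(); gt_rows <- list(); enr_rows <- list()
  for (g in names(groups)) {
    sel <- which(gid %in% groups[[g]])
    counts_rows[[g]] <- data.frame(gene_id = gid[sel], group = g,
                                   n_tfs = pc[sel])
    p_w <- if (length(sel) && (any(pc[sel] > 0) || any(rc > 0))) {
      suppressWarnings(wilcox.test(pc[sel], rc,
                                   alternative = "greater")$p.value)
    } else 1
    gt_rows[[g]] <- data.frame(group = g, p_wilcox = p_w)
    tf_tab <- lapply(tfs, function(tf) {
      a <- length(unique(prom_tf$a_idx[prom_tf$a_idx %in% sel &
                                         prom_tf$tf == tf]))
      b <- length(sel) - a
      cc <- length(unique(rand_tf$a_idx[rand_tf$tf == tf]))
      dd <- n_rand - cc
      f <- fisher_greater(a, b, cc, dd)
      data.frame(group = g, tf = tf, a = a, b = b, c = cc, d = dd,
                 odds_ratio = f$odds_ratio, p = f$p)
    })
    tf_tab <- do.call(rbind, tf_tab)
    tf_tab$q <- bh_fdr(tf_tab$p)
    tf_tab$enriched <- tf_tab$q < 0.05
    enr_rows[[g]] <- tf_tab
  }
  list(counts = do.call(rbind, c(counts_rows, list(make.row.names = FALSE))),
       random_counts = rc,
       group_tests = do.call(rbind, c(gt_rows, list(make.row.names = FALSE))),
       tf_enrichment = do.call(rbind, c(enr_rows,
                                        list(make.row.names = FALSE))))
}

#' Nearest-gene report for lncRNAs
#'
#' For each lncRNA, the nearest subject gene within `max_distance_bp`
#' (default 100 kb). When a subject class map is given, per-group class
#' enrichment over the all-lncRNA background is added (one-sided
#' hypergeometric + BH).
#'
#' @param lncrnas `GRanges` of lncRNA loci with `gene_id`.
#' @param groups Named character vector: lncRNA id to group (MA label).
#' @param subjects `GRanges` of subject loci (coding genes or small RNAs)
#'   with `gene_id`.
#' @param subject_class Optional named character vector: subject gene id
#'   to class (e.g. TF family or small-RNA class).
#' @param max_distance_bp Distance cutoff (default 100 kb).
#' @return List with `nearest` (`data.frame`: `lncrna_id`, `group`,
#'   `nearest_id`, `distance`, `signed_distance`) and `enrichment`
#'   (per-group class enrichment, or `NULL`).
#' @export
closest_gene_report <- function(lncrnas, groups, subjects,
                                subject_class = NULL,
                                max_distance_bp = 100000L) {
  cg <- closest_gene(lncrnas, subjects, max_distance_bp = max_distance_bp)
  ids <- mcols(lncrnas)$gene_id
  nearest <- data.frame(
    lncrna_id = ids,
    group = unname(groups[match(ids, names(groups))]),
    nearest_id = ifelse(is.na(cg$subject_idx), NA_character_,
                        mcols(subjects)$gene_id[cg$subject_idx]),
    distance = cg$distance, signed_distance = cg$signed_distance)
  nearest <- nearest[!is.na(nearest$nearest_id), ]
  rownames(nearest) <- NULL
  enrichment <- NULL
  if (!is.null(subject_class) && nrow(nearest)) {
    cls <- setNames(unname(subject_class[nearest$nearest_id]),
                    nearest$lncrna_id)
    bg <- nearest$lncrna_id
    enrichment <- do.call(rbind, lapply(unique(nearest$group), function(g) {
      res <- category_enrichment(nearest$lncrna_id[nearest$group == g],
                                 cls, bg)
      if (nrow(res)) cbind(group = g, res) else NULL
    }))
  }
  list(nearest = nearest, enrichment = enrichment)
}
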