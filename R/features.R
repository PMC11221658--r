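# Per-gene quantitative features: TPM, the cortical expression filter,
# exon/intron structure, splice-motif strength, TE content, and
# expression-matched gene selection.

#' Compute TPM from a raw count matrix
#'
#' `TPM_i = (q_i / l_i) / sum_j(q_j / l_j) * 1e6` per sample, where `q_i`
#' is the read count of gene i and `l_i` its length in kilobases. Columns
#' sum to one million by construction.
#'
#' @param counts Numeric matrix, genes x samples, non-negative.
#' @param lengths_kb Numeric vector of gene lengths in kilobases, aligned
#'   with the rows of `counts`.
#' @return Matrix of TPM values with the dimnames of `counts`.
#' @examples
#' compute_tpm(cbind(s1 = c(10, 30)), c(1, 2))  # rates (10, 15)
#' @export
compute_tpm <- function(counts, lengths_kb) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(lengths_kb), all(lengths_kb > 0),
            all(counts >= 0))
  rate <- counts / lengths_kb
  denom <- colSums(rate)
  if (any(denom <= 0)) stop("zero counts/length denominator in sample(s): ",
                            paste(colnames(counts)[denom <= 0], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

#' Select cortically expressed genes
#'
#' A gene passes when there exists a developmental window/region pair in
#' which its TPM reaches the threshold in ALL of that pair's samples, or
#' when it appears in at least one single-cell cluster DE table.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param metadata `data.frame` with `sample`, `window`, `region`; every
#'   sample belongs to exactly one window/region pair.
#' @param de_tables List of `data.frame`s with a `gene_id` column (cluster
#'   DE/marker tables); may be empty.
#' @param threshold TPM threshold (default 0.5).
#' @param strict If `FALSE` (default) the comparison is `>=` ("at least");
#'   `TRUE` uses a strict `>`.
#' @return Character vector of passing gene ids.
#' @export
cortical_filter <- function(tpm, metadata, de_tables = list(),
                            threshold = 0.5, strict = FALSE) {
  stopifnot(all(metadata$sample %in% colnames(tpm)))
  pair <- interaction(metadata$window, metadata$region, drop = TRUE)
  cmp <- if (strict) `>` else `>=`
  pass_expr <- rep(FALSE, nrow(tpm))
  for (p in levels(pair)) {
    cols <- metadata$sample[pair == p]
    pass_expr <- pass_expr | apply(cmp(tpm[, cols, drop = FALSE], threshold),
                                   1, all)
  }
  de_genes <- unique(unlist(lapply(de_tables, function(d) d$gene_id)))
  rownames(tpm)[pass_expr | rownames(tpm) %in% de_genes]
}

#' Exon and intron structure statistics
#'
#' First/internal/last exon classes are assigned in transcription order
#' (strand-aware: the rightmost exon of a minus-strand transcript is its
#' first). Single-exon transcripts contribute to no positional class.
#' Introns are the gaps between consecutive exons.
#'
#' @param exons `GRanges` of exons with `transcript_id` and `gene_id`.
#' @return List of `data.frame`s: `transcripts` (`transcript_id`,
#'   `gene_id`, `n_exons`, `tx_length`, `span`), `exons` (`transcript_id`,
#'   `class`, `width`), `introns` (`transcript_id`, `width`), `genes`
#'   (`gene_id`, `n_isoforms`).
#' @export
exon_intron_stats <- function(exons) {
  stopifnot(is(exons, "GRanges"),
            all(c("transcript_id", "gene_id") %in% names(mcols(exons))))
  by_tx <- split(seq_along(exons), mcols(exons)$transcript_id)
  tx_rows <- list(); ex_rows <- list(); in_rows <- list()
  for (tx in names(by_tx)) {
    idx <- by_tx[[tx]][order(start(exons)[by_tx[[tx]]])]
    w <- width(exons)[idx]
    n <- length(idx)
    minus <- as.character(strand(exons))[idx[1L]] == "-"
    cls <- if (n == 1L) "single" else {
      k <- c("first", rep("internal", max(0L, n - 2L)), "last")
      if (minus) rev(k) else k
    }
    ex_rows[[tx]] <- data.frame(transcript_id = tx, class = cls, width = w)
    if (n > 1L) {
      iw <- start(exons)[idx][-1L] - end(exons)[idx][-n] - 1L
      in_rows[[tx]] <- data.frame(transcript_id = tx, width = iw)
    }
    tx_rows[[tx]] <- data.frame(
      transcript_id = tx, gene_id = mcols(exons)$gene_id[idx[1L]],
      n_exons = n, tx_length = sum(w),
      span = max(end(exons)[idx]) - min(start(exons)[idx]) + 1L)
  }
  tx <- do.call(rbind, tx_rows); rownames(tx) <- NULL
  genes <- as.data.frame(table(tx$gene_id), stringsAsFactors = FALSE)
  names(genes) <- c("gene_id", "n_isoforms")
  list(transcripts = tx,
       exons = do.call(rbind, c(ex_rows, list(make.row.names = FALSE))),
       introns = if (length(in_rows))
         do.call(rbind, c(in_rows, list(make.row.names = FALSE)))
       else data.frame(transcript_id = character(0), width = integer(0)),
       genes = genes)
}

#' TE content of gene bodies
#'
#' Keeps TE insertions overlapping a gene by at least `min_overlap_bp`
#' (default 10) and restricted to the configured TE classes. Per insertion,
#' `te_body_fraction` is the overlapped fraction of the TE's own length;
#' per gene, `gene_body_te_fraction` is the summed TE overlap divided by
#' the gene length (capped at 1). Overlap is strand-agnostic.
#'
#' @param genes `GRanges` of gene bodies with a `gene_id` column.
#' @param te_bed `GRanges` of TE insertions with `name` (family) and
#'   optionally `te_class` metadata.
#' @param min_overlap_bp Minimum overlap (default 10 bp).
#' @param keep_classes TE classes retained (`NULL` keeps everything; the
#'   default is the standard whitelist).
#' @return List with `genes` (`gene_id`, `has_te`,
#'   `gene_body_te_fraction`) and `insertions` (`gene_id`, `family`,
#'   `overlap_bp`, `te_body_fraction`).
#' @export
te_content <- function(genes, te_bed, min_overlap_bp = 10L,
                       keep_classes = c("SINE", "LINE", "LTR", "DNA",
                                        "Retroposon", "RC")) {
  stopifnot(is(genes, "GRanges"), is(te_bed, "GRanges"))
  if (!is.null(keep_classes) && "te_class" %in% names(mcols(te_bed))) {
    te_bed <- te_bed[mcols(te_bed)$te_class %in% keep_classes]
  }
  ov <- intersect_intervals(genes, te_bed, min_overlap_bp = min_overlap_bp,
                            same_strand = FALSE)
  ins <- data.frame(
    gene_id = mcols(genes)$gene_id[ov$a_idx],
    family = if ("name" %in% names(mcols(te_bed)))
      as.character(mcols(te_bed)$name)[ov$b_idx] else NA_character_,
    overlap_bp = ov$overlap_bp,
    te_body_fraction = ov$overlap_bp / width(te_bed)[ov$b_idx])
  tot <- tapply(ins$overlap_bp, ins$gene_id, sum)
  frac <- rep(0, length(genes))
  names(frac) <- mcols(genes)$gene_id
  frac[names(tot)] <- pmin(1, tot / width(genes)[match(names(tot),
                                                       mcols(genes)$gene_id)])
  list(genes = data.frame(gene_id = mcols(genes)$gene_id,
                          has_te = mcols(genes)$gene_id %in% ins$gene_id,
                          gene_body_te_fraction = unname(frac)),
       insertions = ins)
}

#' Flag coding sequences that are mostly TE-derived
#'
#' Strand-specific intersection; a CDS is flagged when strictly more than
#' half of its length is covered by TE overlap.
#'
#' @param cds `GRanges` of CDS intervals with a `cds_id` column.
#' @param te_bed `GRanges` of TE insertions.
#' @return Named logical vector per CDS.
#' @export
cds_te_flag <- function(cds, te_bed) {
  ov <- intersect_intervals(cds, te_bed, min_overlap_bp = 1L,
                            same_strand = TRUE)
  tot <- tapply(ov$overlap_bp, ov$a_idx, sum)
  flag <- rep(FALSE, length(cds))
  if (length(tot)) {
    i <- as.integer(names(tot))
    flag[i] <- tot / width(cds)[i] > 0.5
  }
  setNames(flag, mcols(cds)$cds_id)
}

# Minimum-cost order-preserving 1:1 assignment of sorted reference values
# into sorted candidate values (1-D optimal matching); returns candidate
# indices matched to each reference element.
.match_1d <- function(ref, other) {
  n <- length(ref); m <- length(other)
  stopifnot(m >= n)
  ro <- order(ref); oo <- order(other)
  a <- ref[ro]; b <- other[oo]
  cost <- matrix(Inf, n + 1L, m + 1L)
  cost[1L, ] <- 0
  pick <- matrix(FALSE, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in i:m) {
      skip <- cost[i + 1L, j]
      take <- cost[i, j] + abs(a[i] - b[j])
      if (take <= skip) {
        cost[i + 1L, j + 1L] <- take; pick[i + 1L, j + 1L] <- TRUE
      } else cost[i + 1L, j + 1L] <- skip
    }
  }
  sel <- integer(n)
  i <- n + 1L; j <- m + 1L
  while (i > 1L) {
    if (pick[i, j]) { sel[i - 1L] <- j - 1L; i <- i - 1L; j <- j - 1L }
    else j <- j - 1L
  }
  out <- integer(n)
  out[ro] <- oo[sel]
  out
}

#' Select expression-matched gene subsets
#'
#' For each non-reference group, finds the 1:1 assignment to the reference
#' genes that minimizes the total absolute difference of a scalar covariate
#' (mean variance-stabilized expression), via optimal one-dimensional
#' matching. All returned groups have the reference group's size.
#'
#' @param groups Named list: group name to character vector of gene ids.
#' @param covariate Named numeric vector: gene id to matching covariate.
#' @param reference_group Name of the reference group (must be no larger
#'   than any other group).
#' @return Named list of matched gene-id vectors (reference included,
#'   unchanged); element order follows the reference genes.
#' @export
match_expression <- function(groups, covariate, reference_group) {
  stopifnot(reference_group %in% names(groups))
  ref_ids <- groups[[reference_group]]
  stopifnot(all(unlist(groups) %in% names(covariate)))
  out <- list()
  out[[reference_group]] <- ref_ids
  for (g in setdiff(names(groups), reference_group)) {
    ids <- groups[[g]]
    if (length(ids) < length(ref_ids)) {
      stop("group '", g, "' is smaller than the reference group")
    }
    sel <- .match_1d(covariate[ref_ids], covariate[ids])
    out[[g]] <- ids[sel]
  }
  out
}

#' Count cell clusters in which each gene is a marker
#'
#' Genes absent from every table are excluded. The binned distribution
#' groups counts of six or more as `"6+"`.
#'
#' @param de_tables Named list of per-cluster marker `data.frame`s with a
#'   `gene_id` column.
#' @return List with `counts` (named integer vector) and `bins` (named
#'   factor over `1`..`5`, `6+`).
#' @export
specificity_counts <- function(de_tables) {
  genes <- unlist(lapply(de_tables, function(d) unique(d$gene_id)))
  if (!length(genes)) {
    return(list(counts = integer(0),
                bins = factor(character(0), levels = c(1:5, "6+"))))
  }
  counts <- table(genes)
  counts <- setNames(as.integer(counts), names(counts))
  bins <- ifelse(counts >= 6L, "6+", as.character(counts))
  list(counts = counts,
       bins = factor(setNames(bins, names(counts)), levels = c(1:5, "6+")))
}
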