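# Thresholded coordinate lifting over UCSC alignment chains.
#
# minMatch is interpreted as the fraction of query bases that remap through
# aligned blocks; minBlocks as the fraction of query sub-blocks that remap,
# where the query interval is partitioned into maximal segments by the
# chain's aligned-block/gap structure (segments outside the chain span or
# inside source gaps do not map). This is the documented contract standing
# in for the liftOver flags of the same names.

# 0-based start offsets of each aligned block on the source and target side.
.chain_block_coords <- function(ch) {
  b <- ch$blocks
  ss <- ch$source_start + cumsum(c(0L, head(b$size + b$dsource, -1L)))
  ts <- ch$target_start + cumsum(c(0L, head(b$size + b$dtarget, -1L)))
  list(source_start = ss, target_start = ts, size = b$size)
}

# Deterministic chain choice: highest score among chains overlapping the
# query, preferring chains that cover the query midpoint; ties broken by
# chain_id.
.select_chain <- function(chains, chrom, q0_start, q0_end) {
  ov <- vapply(chains, function(ch) {
    ch$source_chrom == chrom && ch$source_start < q0_end &&
      ch$source_end > q0_start
  }, logical(1))
  cand <- chains[ov]
  if (!length(cand)) return(NULL)
  mid <- (q0_start + q0_end - 1L) %/% 2L
  covers <- vapply(cand, function(ch) {
    ch$source_start <= mid && mid < ch$source_end
  }, logical(1))
  if (any(covers)) cand <- cand[covers]
  scores <- vapply(cand, function(ch) ch$score, numeric(1))
  ids <- vapply(cand, function(ch) ch$chain_id, character(1))
  cand[[order(-scores, ids)[1L]]]
}

# Core lift arithmetic on plain 0-based coordinates; returns target
# coordinates still 0-based half-open on the forward strand, or NULL target
# when the thresholds are not met. Used by lift_interval() and by the
# pipeline's inner loops, which avoid GRanges construction per call.
# `bc_cache` optionally holds precomputed .chain_block_coords() per chain
# (aligned with `chains`) for repeated lifting over the same chain set.
.lift0 <- function(chains, chrom, q0s, q0e, min_match, min_blocks,
                   bc_cache = NULL) {
  miss <- list(t_chrom = NA_character_, t0s = NA_integer_, t0e = NA_integer_,
               flip = FALSE, base_frac = 0, block_frac = 0,
               chain_id = NA_character_, ok = FALSE)
  qw <- q0e - q0s
  sel <- which(vapply(chains, function(ch) {
    ch$source_chrom == chrom && ch$source_start < q0e && ch$source_end > q0s
  }, logical(1)))
  if (!length(sel)) return(miss)
  ch <- .select_chain(chains[sel], chrom, q0s, q0e)
  ci <- sel[vapply(chains[sel], function(x)
    identical(x$chain_id, ch$chain_id), logical(1))][1L]
  bc <- if (!is.null(bc_cache)) bc_cache[[ci]] else .chain_block_coords(ch)
  os <- pmax(bc$source_start, q0s)
  oe <- pmin(bc$source_start + bc$size, q0e)
  hit <- which(oe > os)
  if (!length(hit)) return(miss)
  osh <- os[hit]; oeh <- oe[hit]
  matched <- sum(oeh - osh)
  toff_first <- bc$target_start[hit] + (osh - bc$source_start[hit])
  toff_last <- toff_first + (oeh - osh) - 1L
  tmin <- min(toff_first); tmax <- max(toff_last)
  # unmapped query sub-blocks: maximal runs of query bases outside aligned
  # blocks (leading, internal, trailing), counted arithmetically
  n_gaps <- (q0s < osh[1L]) + (q0e > oeh[length(oeh)]) +
    if (length(osh) > 1L) sum(osh[-1L] > oeh[-length(oeh)]) else 0L
  base_frac <- matched / qw
  block_frac <- length(hit) / (length(hit) + n_gaps)
  out <- list(t_chrom = ch$target_chrom, t0s = NA_integer_, t0e = NA_integer_,
              flip = ch$target_strand == "-", base_frac = base_frac,
              block_frac = block_frac, chain_id = ch$chain_id, ok = FALSE)
  if (base_frac < min_match || block_frac < min_blocks) return(out)
  if (ch$target_strand == "+") {
    out$t0s <- tmin; out$t0e <- tmax + 1L
  } else {
    out$t0s <- ch$target_size - 1L - tmax
    out$t0e <- ch$target_size - tmin
  }
  out$ok <- TRUE
  out
}

#' Lift one interval through an alignment chain set
#'
#' Maps a query interval to target-genome coordinates through the
#' best-scoring covering chain, reporting the fraction of query bases and
#' query sub-blocks that remap. The lifted interval is the span from the
#' first to the last mapped base in target coordinates, normalized to the
#' forward strand; it is absent when either fraction falls below its
#' threshold (`min_match`, `min_blocks` — the liftOver `-minMatch` /
#' `-minBlocks` semantics).
#'
#' @param chains List of chain records from [read_chain()].
#' @param query A length-1 `GRanges`.
#' @param min_match Minimum fraction of query bases that must remap.
#' @param min_blocks Minimum fraction of query sub-blocks that must remap.
#' @return A list with `lifted` (`GRanges` of length 1, or `NULL`),
#'   `matched_base_fraction`, `matched_block_fraction`, `chain_id`.
#' @examples
#' ch <- list(chain_id = "1", score = 1000,
#'   source_chrom = "chrQ", source_size = 1000L, source_strand = "+",
#'   source_start = 0L, source_end = 1000L,
#'   target_chrom = "chrT", target_size = 1000L, target_strand = "+",
#'   target_start = 0L, target_end = 1000L,
#'   blocks = data.frame(size = 1000L, dsource = 0L, dtarget = 0L))
#' q <- GenomicRanges::GRanges("chrQ", IRanges::IRanges(101, 200))
#' lift_interval(list(ch), q, 0.1, 0.01)
#' @export
lift_interval <- function(chains, query, min_match, min_blocks) {
  stopifnot(is(query, "GRanges"), length(query) == 1L,
            min_match > 0, min_match <= 1, min_blocks > 0, min_blocks <= 1)
  r <- .lift0(chains, as.character(seqnames(query)), start(query) - 1L,
              end(query), min_match, min_blocks)
  if (!r$ok) {
    return(list(lifted = NULL, matched_base_fraction = r$base_frac,
                matched_block_fraction = r$block_frac, chain_id = r$chain_id))
  }
  qs <- as.character(strand(query))
  out_strand <- if (r$flip) ifelse(qs == "+", "-", ifelse(qs == "-", "+", "*"))
                else qs
  lifted <- GRanges(r$t_chrom, IRanges(r$t0s + 1L, r$t0e), strand = out_strand)
  list(lifted = lifted, matched_base_fraction = r$base_frac,
       matched_block_fraction = r$block_frac, chain_id = r$chain_id)
}

#' Lift many intervals through an alignment chain set
#'
#' Vectorized front end to [lift_interval()].
#'
#' @inheritParams lift_interval
#' @param query A `GRanges`.
#' @return `data.frame` with one row per query: `target_chrom`,
#'   `target_start`, `target_end` (1-based closed; `NA` when not lifted),
#'   `target_strand`, `matched_base_fraction`, `matched_block_fraction`,
#'   `lifted` (logical), `chain_id`.
#' @export
lift_intervals <- function(chains, query, min_match, min_blocks) {
  stopifnot(is(query, "GRanges"))
  n <- length(query)
  out <- data.frame(
    target_chrom = rep(NA_character_, n), target_start = NA_integer_,
    target_end = NA_integer_, target_strand = NA_character_,
    matched_base_fraction = 0, matched_block_fraction = 0,
    lifted = FALSE, chain_id = NA_character_)
  for (i in seq_len(n)) {
    r <- lift_interval(chains, query[i], min_match, min_blocks)
    out$matched_base_fraction[i] <- r$matched_base_fraction
    out$matched_block_fraction[i] <- r$matched_block_fraction
    out$chain_id[i] <- r$chain_id
    if (!is.null(r$lifted)) {
      out$lifted[i] <- TRUE
      out$target_chrom[i] <- as.character(seqnames(r$lifted))
      out$target_start[i] <- start(r$lifted)
      out$target_end[i] <- end(r$lifted)
      out$target_strand[i] <- as.character(strand(r$lifted))
    }
  }
  out
}
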