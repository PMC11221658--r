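# Independent brute-force oracles used to validate the interval algebra,
# chain lifting, matching and enrichment code. These deliberately use
# per-base loops and direct enumeration, never the implementation under
# test.

# Per-base coverage of a set of 1-based closed intervals on one chromosome.
oracle_coverage <- function(starts, ends, len) {
  cov <- logical(len)
  for (i in seq_along(starts)) cov[starts[i]:ends[i]] <- TRUE
  cov
}

# Per-base set operations.
oracle_union_bases <- function(a_start, a_end, len) {
  which(oracle_coverage(a_start, a_end, len))
}
oracle_subtract_bases <- function(a_start, a_end, b_start, b_end, len) {
  a <- oracle_coverage(a_start, a_end, len)
  b <- if (length(b_start)) oracle_coverage(b_start, b_end, len)
       else logical(len)
  which(a & !b)
}

# All-pairs overlap widths.
oracle_overlaps <- function(a_start, a_end, b_start, b_end) {
  out <- NULL
  for (i in seq_along(a_start)) {
    for (j in seq_along(b_start)) {
      ov <- min(a_end[i], b_end[j]) - max(a_start[i], b_start[j]) + 1L
      if (ov > 0L) out <- rbind(out, c(i, j, ov))
    }
  }
  out
}

# Exhaustive nearest-subject scan (1-based closed, single chromosome).
oracle_nearest <- function(q_start, q_end, s_start, s_end) {
  best_d <- Inf; best_j <- NA_integer_
  for (j in seq_along(s_start)) {
    # gap = number of bases strictly between the two closed intervals
    d <- if (s_end[j] >= q_start && s_start[j] <= q_end) 0L
         else if (s_end[j] < q_start) q_start - s_end[j] - 1L
         else s_start[j] - q_end - 1L
    if (d < best_d || (d == best_d && !is.na(best_j) &&
                       s_start[j] < s_start[best_j])) {
      best_d <- d; best_j <- j
    }
  }
  list(j = best_j, d = best_d)
}

# Per-base chain mapping oracle: walks the chain block structure base by
# base and records where each source base of [q0s, q0e) lands (0-based).
oracle_lift <- function(chain, q0s, q0e) {
  spos <- chain$source_start
  tpos <- chain$target_start
  mapped_t <- integer(0)
  n_mapped <- 0L
  b <- chain$blocks
  for (k in seq_len(nrow(b))) {
    for (off in seq_len(b$size[k]) - 1L) {
      src <- spos + off
      if (src >= q0s && src < q0e) {
        mapped_t <- c(mapped_t, tpos + off)
        n_mapped <- n_mapped + 1L
      }
    }
    spos <- spos + b$size[k] + b$dsource[k]
    tpos <- tpos + b$size[k] + b$dtarget[k]
  }
  if (!n_mapped) return(list(n = 0L))
  t0s <- min(mapped_t); t0e <- max(mapped_t) + 1L
  if (chain$target_strand == "-") {
    fs <- chain$target_size - (max(mapped_t) + 1L)
    fe <- chain$target_size - min(mapped_t)
    t0s <- fs; t0e <- fe
  }
  list(n = n_mapped, t0s = t0s, t0e = t0e,
       base_frac = n_mapped / (q0e - q0s))
}

# Upper hypergeometric tail by direct pmf summation with choose().
oracle_hyper_tail <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  ks <- max(0L, k - n):min(k, m)
  pmf <- choose(m, ks) * choose(n, k - ks) / choose(m + n, k)
  sum(pmf[ks >= a])
}

# Minimum-cost injection of ref into cand by exhaustive recursion.
oracle_min_assignment <- function(ref, cand) {
  ref <- unname(ref); cand <- unname(cand)
  n <- length(ref); m <- length(cand)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- acc; return() }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + abs(ref[i] - cand[j]))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(m), 0)
  best
}

# Random interval set on a toy chromosome (1-based closed).
random_intervals <- function(n, len, max_w = 500L) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- sample.int(len - max_w, n, replace = TRUE)
  data.frame(start = s, end = s + w - 1L)
}

toy_granges <- function(df, chrom = "chr1", strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end),
                         strand = strand)
}

# A small synthetic chain on toy genomes: alternating aligned blocks and
# gaps with the given sizes.
toy_chain <- function(sizes, dsource, dtarget, source_start = 0L,
                      target_start = 0L, source_size = 10000L,
                      target_size = 10000L, target_strand = "+",
                      chain_id = "1", score = 1000,
                      source_chrom = "chrQ", target_chrom = "chrT") {
  n <- length(sizes)
  stopifnot(length(dsource) == n, length(dtarget) == n,
            dsource[n] == 0L, dtarget[n] == 0L)
  list(chain_id = chain_id, score = score,
       source_chrom = source_chrom, source_size = source_size,
       source_strand = "+", source_start = source_start,
       source_end = source_start + sum(sizes + dsource),
       target_chrom = target_chrom, target_size = target_size,
       target_strand = target_strand, target_start = target_start,
       target_end = target_start + sum(sizes + dtarget),
       blocks = data.frame(size = sizes, dsource = dsource,
                           dtarget = dtarget))
}
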