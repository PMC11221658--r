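#' Merge genomic intervals into a disjoint sorted union
#'
#' Book-ended intervals (where one ends exactly where the next begins) are
#' merged, matching the exon-union intent of metagene construction.
#'
#' @param x A `GRanges`.
#' @param strand_aware If `TRUE`, intervals are only merged with others on
#'   the same strand; otherwise strand is ignored and the result is
#'   unstranded.
#' @return A `GRanges` of disjoint, sorted intervals covering exactly the
#'   union of `x`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 16), c(20, 30)))
#' merge_intervals(gr)
#' @export
merge_intervals <- function(x, strand_aware = FALSE) {
  stopifnot(is(x, "GRanges"))
  if (length(x) == 0L) return(x)
  GenomicRanges::reduce(x, ignore.strand = !strand_aware)
}

#' Subtract one interval set from another (set semantics)
#'
#' Returns the bases covered by `a` but not by `b`, as disjoint sorted
#' intervals. Used to remove transposable-element insertions from metagene
#' models before the TE-masked homology pass. Zero-length results are never
#' emitted.
#'
#' @param a,b `GRanges` objects.
#' @param ignore_strand If `TRUE` (default), strand plays no role and the
#'   result is unstranded; matches strand-agnostic TE masking.
#' @return `GRanges` with the per-base set difference `a \\ b`.
#' @export
subtract_intervals <- function(a, b, ignore_strand = TRUE) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  if (length(a) == 0L) return(a)
  GenomicRanges::setdiff(a, b, ignore.strand = ignore_strand)
}

#' Report overlapping interval pairs above a minimum overlap
#'
#' Emulates `bedtools intersect -wo` (and `-s` when `same_strand = TRUE`):
#' every pair of intervals from `a` and `b` overlapping by at least
#' `min_overlap_bp` bases is reported with its overlap width.
#'
#' @param a,b `GRanges` objects.
#' @param min_overlap_bp Minimum overlap in bases (>= 1).
#' @param same_strand If `TRUE`, only same-strand pairs are reported.
#' @return A `data.frame` with columns `a_idx`, `b_idx`, `overlap_bp`.
#' @export
intersect_intervals <- function(a, b, min_overlap_bp = 1L, same_strand = FALSE) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), min_overlap_bp >= 1L)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap_bp,
                                      ignore.strand = !same_strand)
  qi <- queryHits(hits); si <- subjectHits(hits)
  if (same_strand && length(hits)) {
    # findOverlaps treats "*" as matching both strands; require strict equality
    keep <- as.character(strand(a))[qi] == as.character(strand(b))[si]
    qi <- qi[keep]; si <- si[keep]
  }
  ov <- integer(length(qi))
  if (length(qi)) {
    ov <- pmin(end(a)[qi], end(b)[si]) - pmax(start(a)[qi], start(b)[si]) + 1L
  }
  data.frame(a_idx = qi, b_idx = si, overlap_bp = ov)
}

#' Find the closest subject interval within a maximum distance
#'
#' For each query, returns the minimum-distance subject on the same
#' chromosome (distance 0 when overlapping), or no hit when the nearest
#' subject lies farther than `max_distance_bp` (default 100 kb, the window
#' used when collecting protein-coding genes around lncRNAs). Ties are
#' broken deterministically by smaller subject start, then subject index.
#'
#' @param query,subjects `GRanges` objects.
#' @param max_distance_bp Maximum distance in bp; nearer-or-equal subjects
#'   are reported.
#' @param ignore_strand If `TRUE` (default) strand plays no role.
#' @return `data.frame` with one row per query: `query_idx`, `subject_idx`
#'   (NA if none within range), `distance` (unsigned gap in bp) and
#'   `signed_distance` (negative when the subject lies left of the query).
#' @export
closest_gene <- function(query, subjects, max_distance_bp = 100000L,
                         ignore_strand = TRUE) {
  stopifnot(is(query, "GRanges"), is(subjects, "GRanges"))
  n <- length(query)
  out <- data.frame(query_idx = seq_len(n), subject_idx = NA_integer_,
                    distance = NA_integer_, signed_distance = NA_integer_)
  if (n == 0L || length(subjects) == 0L) return(out)
  d <- GenomicRanges::distanceToNearest(query, subjects, select = "all",
                                        ignore.strand = ignore_strand)
  if (length(d) == 0L) return(out)
  qi <- queryHits(d); si <- subjectHits(d)
  dist <- mcols(d)$distance
  ord <- order(qi, dist, start(subjects)[si], si)
  qi <- qi[ord]; si <- si[ord]; dist <- dist[ord]
  first <- !duplicated(qi)
  qi <- qi[first]; si <- si[first]; dist <- dist[first]
  keep <- dist <= max_distance_bp
  qi <- qi[keep]; si <- si[keep]; dist <- dist[keep]
  out$subject_idx[qi] <- si
  out$distance[qi] <- dist
  sgn <- ifelse(dist == 0L, 0L,
                ifelse(end(subjects)[si] < start(query)[qi], -1L, 1L))
  out$signed_distance[qi] <- sgn * dist
  out
}

#' Randomly relocate intervals within their chromosomes
#'
#' Emulates `bedtools shuffle` restricted to the original chromosome: each
#' interval keeps its length and chromosome and receives a uniformly drawn
#' new start. Used to build the random-region null for promoter TF analyses.
#'
#' @param x `GRanges` to shuffle.
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param seed Integer seed; identical seeds give identical output. The
#'   caller's RNG state is left untouched.
#' @return `GRanges` with the same lengths, strands and chromosomes, new
#'   uniform starts.
#' @export
shuffle_intervals <- function(x, chrom_sizes, seed) {
  stopifnot(is(x, "GRanges"), !is.null(names(chrom_sizes)))
  sizes <- chrom_sizes[as.character(seqnames(x))]
  if (anyNA(sizes)) stop("interval on chromosome missing from chrom_sizes")
  w <- width(x)
  if (any(w > sizes)) stop("interval longer than its chromosome")
  starts <- .with_seed(seed, {
    floor(runif(length(x), min = 1, max = sizes - w + 1 + 1))
  })
  GRanges(seqnames(x), IRanges(as.integer(starts), width = w),
          strand = strand(x))
}
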