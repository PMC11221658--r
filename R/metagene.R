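# Metagene construction: the positional unit of all homology reasoning is
# the strand-aware union of all exon intervals of a gene's isoforms.

#' Merge a gene's isoform exons into a metagene
#'
#' @param transcripts `GRanges` of exons from one gene (any number of
#'   isoforms). All exons must share one chromosome and one strand.
#' @return `GRanges` of disjoint, sorted exon-union intervals carrying the
#'   gene's strand (and `gene_id` metadata when present in the input).
#' @export
build_metagene <- function(transcripts) {
  stopifnot(is(transcripts, "GRanges"), length(transcripts) >= 1L)
  if (length(unique(as.character(strand(transcripts)))) != 1L) {
    stop("mixed strands within one gene")
  }
  if (length(unique(as.character(seqnames(transcripts)))) != 1L) {
    stop("exons of one gene on several chromosomes")
  }
  mg <- GenomicRanges::reduce(transcripts, ignore.strand = FALSE)
  if ("gene_id" %in% names(mcols(transcripts))) {
    mcols(mg)$gene_id <- mcols(transcripts)$gene_id[1L]
  }
  mg
}

#' Remove TE insertions from a metagene model
#'
#' Subtracts TE intervals from the metagene (strand-agnostic, matching the
#' repeat-masking step before the TE-masked homology pass). The result may
#' be empty for a fully TE-derived lncRNA; such genes are skipped in the
#' TE-masked pass and caught by the TE-retained pass.
#'
#' @param metagene `GRanges` from [build_metagene()].
#' @param te_records `GRanges` of TE insertions.
#' @return `GRanges`, possibly empty; strand and `gene_id` are preserved.
#' @export
mask_tes <- function(metagene, te_records) {
  stopifnot(is(metagene, "GRanges"), is(te_records, "GRanges"))
  if (length(metagene) == 0L) return(metagene)
  res <- subtract_intervals(metagene, te_records, ignore_strand = TRUE)
  strand(res) <- as.character(strand(metagene))[1L]
  if ("gene_id" %in% names(mcols(metagene))) {
    mcols(res)$gene_id <- if (length(res)) mcols(metagene)$gene_id[1L]
                          else character(0)
  }
  res
}

# Per-gene metagenes for a whole exon annotation; returns a GRangesList
# named by gene_id.
.metagenes_by_gene <- function(exons, biotype = NULL) {
  if (!is.null(biotype)) {
    exons <- exons[mcols(exons)$gene_biotype %in% biotype]
  }
  by_gene <- split(exons, mcols(exons)$gene_id)
  GenomicRanges::reduce(by_gene)
}

# Span (range) of each metagene in a GRangesList, as a flat GRanges with
# gene_id and strand metadata.
.metagene_spans <- function(mglist, strands) {
  rng <- unlist(range(mglist, ignore.strand = FALSE))
  mcols(rng)$gene_id <- names(rng)
  names(rng) <- NULL
  rng
}
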