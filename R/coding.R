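# Consensus coding-potential classification.
#
# A transcript is a lncRNA when at most one of the three coding-potential
# calculators calls it coding AND no bona fide ORF was found. A locus is a
# lncRNA when all of its transcripts are lncRNAs, or when the reference
# annotation already marks the locus as a lncRNA gene.

#' Classify one transcript by the coding-potential consensus rule
#'
#' @param calls Logical vector of length 3: does each calculator call the
#'   transcript protein-coding?
#' @param orf_found Logical: was a bona fide ORF identified?
#' @return `"lncRNA"` or `"non_lncRNA"`.
#' @examples
#' classify_transcript(c(FALSE, FALSE, FALSE), FALSE)  # lncRNA
#' classify_transcript(c(TRUE, FALSE, FALSE), FALSE)   # still lncRNA
#' classify_transcript(c(TRUE, TRUE, FALSE), FALSE)    # non_lncRNA
#' @export
classify_transcript <- function(calls, orf_found) {
  stopifnot(is.logical(calls), length(calls) == 3L, !anyNA(calls),
            is.logical(orf_found), length(orf_found) == 1L, !is.na(orf_found))
  if (sum(calls) <= 1L && !orf_found) "lncRNA" else "non_lncRNA"
}

#' Classify a locus from its transcript classes and reference biotype
#'
#' @param transcript_classes Character vector of `"lncRNA"`/`"non_lncRNA"`
#'   per transcript of the locus (at least one).
#' @param ref_biotype Reference-annotation biotype of the locus, or `NA`;
#'   a reference `"lncRNA"` biotype overrides the all-transcripts rule.
#' @return `"lncRNA"` or `"non_lncRNA"`.
#' @export
classify_locus <- function(transcript_classes, ref_biotype = NA_character_) {
  if (length(transcript_classes) == 0L) stop("locus with no transcripts")
  stopifnot(all(transcript_classes %in% c("lncRNA", "non_lncRNA")))
  if (all(transcript_classes == "lncRNA") ||
      (!is.na(ref_biotype) && ref_biotype == "lncRNA")) "lncRNA"
  else "non_lncRNA"
}

#' Apply the coding-potential consensus to a call table
#'
#' Vectorized transcript- and locus-level classification of a coding-call
#' table with columns `transcript_id`, `gene_id`, `cpc_coding`,
#' `cpat_coding`, `feelnc_coding`, `orf_found` and optionally `ref_biotype`.
#'
#' @param calls `data.frame` in the schema above.
#' @return List with `transcripts` (`data.frame`: `transcript_id`, `class`)
#'   and `loci` (`data.frame`: `gene_id`, `class`).
#' @export
classify_coding_calls <- function(calls) {
  need <- c("transcript_id", "gene_id", "cpc_coding", "cpat_coding",
            "feelnc_coding", "orf_found")
  stopifnot(all(need %in% names(calls)))
  votes <- calls$cpc_coding + calls$cpat_coding + calls$feelnc_coding
  tclass <- ifelse(votes <= 1L & !calls$orf_found, "lncRNA", "non_lncRNA")
  ref <- if ("ref_biotype" %in% names(calls)) calls$ref_biotype
         else rep(NA_character_, nrow(calls))
  loci <- vapply(split(seq_len(nrow(calls)), calls$gene_id), function(idx) {
    rb <- ref[idx]
    rb <- if (any(!is.na(rb))) rb[!is.na(rb)][1L] else NA_character_
    classify_locus(tclass[idx], rb)
  }, character(1))
  list(transcripts = data.frame(transcript_id = calls$transcript_id,
                                class = tclass),
       loci = data.frame(gene_id = names(loci), class = unname(loci)))
}
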