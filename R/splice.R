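# Splice-site motif scoring.
#
# Donor sites are scored on a 9-mer (last 3 exonic + first 6 intronic
# bases), acceptor sites on a 15-mer (last 12 intronic + first 3 exonic
# bases), both in transcription orientation. "Strength" is operationalized
# as a log-odds score under position weight matrices trained on the
# annotation's own protein-coding splice sites (uniform background,
# pseudocount 1); a site is "strong" when its score reaches the 75th
# percentile of the coding-gene sites of the same type. This is a declared
# stand-in definition: no specific published scoring scheme is claimed.

.DONOR_LEN <- 9L
.ACCEPTOR_LEN <- 15L

# Extract donor/acceptor k-mers for every intron of every transcript.
.splice_site_kmers <- function(exons, genome) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  by_tx <- split(seq_along(exons), mcols(exons)$transcript_id)
  rows <- list()
  for (tx in names(by_tx)) {
    idx <- by_tx[[tx]][order(start(exons)[by_tx[[tx]]])]
    if (length(idx) < 2L) next
    chrom <- as.character(seqnames(exons))[idx[1L]]
    if (!chrom %in% names(genome)) stop("no sequence for ", chrom)
    sq <- genome[[chrom]]
    minus <- as.character(strand(exons))[idx[1L]] == "-"
    is_ <- end(exons)[idx][-length(idx)] + 1L   # intron starts
    ie_ <- start(exons)[idx][-1L] - 1L          # intron ends
    for (k in seq_along(is_)) {
      if (minus) {
        dw <- c(ie_[k] - 5L, ie_[k] + 3L)
        aw <- c(is_[k] - 3L, is_[k] + 11L)
      } else {
        dw <- c(is_[k] - 3L, is_[k] + 5L)
        aw <- c(ie_[k] - 11L, ie_[k] + 3L)
      }
      if (min(dw, aw) < 1L || max(dw, aw) > length(sq)) {
        stop("splice-site window outside sequence on ", chrom)
      }
      donor <- Biostrings::subseq(sq, dw[1L], dw[2L])
      accep <- Biostrings::subseq(sq, aw[1L], aw[2L])
      i2 <- Biostrings::subseq(sq, is_[k], is_[k] + 1L)
      e2 <- Biostrings::subseq(sq, ie_[k] - 1L, ie_[k])
      if (minus) {
        donor <- Biostrings::reverseComplement(donor)
        accep <- Biostrings::reverseComplement(accep)
        first2 <- as.character(Biostrings::reverseComplement(e2))
        last2 <- as.character(Biostrings::reverseComplement(i2))
      } else {
        first2 <- as.character(i2)
        last2 <- as.character(e2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx,
        gene_id = mcols(exons)$gene_id[idx[1L]],
        biotype = if ("gene_biotype" %in% names(mcols(exons)))
          mcols(exons)$gene_biotype[idx[1L]] else NA_character_,
        intron = k,
        donor = as.character(donor), acceptor = as.character(accep),
        canonical = first2 %in% c("GT", "GC") && last2 == "AG")
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      biotype = character(0), intron = integer(0),
                      donor = character(0), acceptor = character(0),
                      canonical = logical(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Log-odds PWM from a character vector of equal-length k-mers.
.train_pwm <- function(kmers, len) {
  m <- matrix(1, nrow = 4, ncol = len,
              dimnames = list(c("A", "C", "G", "T"), NULL))  # pseudocount
  for (km in kmers) {
    b <- strsplit(km, "")[[1]]
    ok <- b %in% rownames(m)
    for (j in which(ok)) m[b[j], j] <- m[b[j], j] + 1
  }
  log2(sweep(m, 2, colSums(m), "/") / 0.25)
}

.score_pwm <- function(kmers, pwm) {
  vapply(kmers, function(km) {
    b <- strsplit(km, "")[[1]]
    sum(vapply(seq_along(b), function(j) {
      if (b[j] %in% rownames(pwm)) pwm[b[j], j] else 0
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score splice-site motif strength
#'
#' Trains donor and acceptor position weight matrices on the protein-coding
#' splice sites of the supplied annotation, scores every splice site, flags
#' canonical introns (GT..AG or GC..AG) and calls a site "strong" when its
#' score reaches the 75th percentile of the coding-gene sites of the same
#' type.
#'
#' @param exons `GRanges` of exons with `transcript_id`, `gene_id` and
#'   `gene_biotype` metadata.
#' @param genome Named `DNAStringSet` of chromosome sequences.
#' @return List with `sites` (per splice site: ids, `canonical`,
#'   `donor_score`, `acceptor_score`, `donor_strong`, `acceptor_strong`)
#'   and `pwm` (the trained matrices and thresholds).
#' @export
splice_motif_strength <- function(exons, genome) {
  sites <- .splice_site_kmers(exons, genome)
  if (!nrow(sites)) {
    return(list(sites = sites, pwm = NULL))
  }
  coding <- sites$biotype %in% "protein_coding"
  if (!any(coding)) stop("no protein-coding splice sites to train on")
  pwm_d <- .train_pwm(sites$donor[coding], .DONOR_LEN)
  pwm_a <- .train_pwm(sites$acceptor[coding], .ACCEPTOR_LEN)
  sites$donor_score <- .score_pwm(sites$donor, pwm_d)
  sites$acceptor_score <- .score_pwm(sites$acceptor, pwm_a)
  thr_d <- stats::quantile(sites$donor_score[coding], 0.75, names = FALSE)
  thr_a <- stats::quantile(sites$acceptor_score[coding], 0.75, names = FALSE)
  sites$donor_strong <- sites$donor_score >= thr_d
  sites$acceptor_strong <- sites$acceptor_score >= thr_a
  list(sites = sites,
       pwm = list(donor = pwm_d, acceptor = pwm_a,
                  donor_threshold = thr_d, acceptor_threshold = thr_a))
}
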