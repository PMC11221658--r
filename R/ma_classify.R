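# Minimal evolutionary age classification by reciprocal positional
# conservation.
#
# For every query lncRNA metagene and every target species, the (optionally
# TE-masked) metagene span is lifted through the pairwise chains; a lifted
# locus matches a target lncRNA when it overlaps it on the same strand and
# the two loci share at least one neighboring one-to-one protein-coding
# ortholog on the same relative side and strand. Only pairs recovered in
# both lift directions (reciprocal) count as homologs. The minimal age is
# the deepest species with a reciprocal homolog; public synteny annotations
# override upward (oldest label wins); lncRNAs with only nonreciprocal
# signals and no public record are "uncertain"; lncRNAs with no signal at
# all are "human_specific" (query-specific).
#
# The inner loops work on plain data.frames of locus spans (one row per
# gene: chrom, start, end, strand, gene_id); GRanges appear only at the
# exported API surface.

#' Combine liftOver and sequence-mapping transfers
#'
#' The lifted locus is used when present; otherwise an externally supplied
#' sequence-mapping locus (e.g. from a spliced aligner) is used; otherwise
#' nothing.
#'
#' @param lift Result of [lift_interval()] (a list with `lifted`).
#' @param seq_map A `GRanges` of length 1 from whole-gene sequence mapping,
#'   or `NULL`.
#' @return `GRanges` of length 1, or `NULL`.
#' @export
combine_transfers <- function(lift, seq_map = NULL) {
  if (!is.null(lift$lifted)) return(lift$lifted)
  if (!is.null(seq_map)) return(seq_map)
  NULL
}

#' Keep only reciprocally recovered homolog pairs
#'
#' @param pairs_q_to_t,pairs_t_to_q `data.frame`s with columns `query_id`,
#'   `target_id` from the two lift directions (both oriented as
#'   query-species id, target-species id).
#' @return `data.frame` of pairs present in both directions.
#' @export
reciprocal_filter <- function(pairs_q_to_t, pairs_t_to_q) {
  key_f <- paste(pairs_q_to_t$query_id, pairs_q_to_t$target_id)
  key_r <- paste(pairs_t_to_q$query_id, pairs_t_to_q$target_id)
  out <- pairs_q_to_t[key_f %in% key_r, c("query_id", "target_id")]
  rownames(out) <- NULL
  out
}

#' Merge the TE-masked and TE-retained pass assignments
#'
#' Per lncRNA the older of the two draft labels is kept (age order
#' `300 > 90 > 25 > apes > human_specific`); a label found by only one pass
#' is kept as is.
#'
#' @param te_masked,te_retained Named character vectors of draft labels
#'   (`NA` = no homolog found), over the same lncRNA universe.
#' @return Named character vector of merged draft labels.
#' @export
merge_passes <- function(te_masked, te_retained) {
  stopifnot(setequal(names(te_masked), names(te_retained)))
  te_retained <- te_retained[names(te_masked)]
  older <- .age_rank(te_retained) > .age_rank(te_masked)
  older[is.na(te_masked)] <- TRUE
  older[is.na(te_retained)] <- FALSE
  out <- te_masked
  out[older] <- te_retained[older]
  out
}

#' Merge pipeline assignments with a public synteny table
#'
#' The oldest classification wins; provenance records whether the final
#' label came from the pipeline, the public table, or both agreeing.
#'
#' @param ours Named character vector of pipeline draft labels (`NA` = no
#'   homolog found).
#' @param public Named character vector: lncRNA id to claimed minimal-age
#'   label (from public synteny databases); may cover any subset.
#' @return `data.frame` with `lncrna_id`, `label` (`NA` when neither source
#'   has one), `provenance` in `{pipeline, public_db, merged}`.
#' @export
merge_public <- function(ours, public = character(0)) {
  if (length(public)) {
    bad <- !public %in% .MA_LEVELS
    if (any(bad)) {
      stop("unknown public synteny labels for: ",
           paste(names(public)[bad], collapse = ", "))
    }
  }
  pub <- public[match(names(ours), names(public))]
  take_pub <- !is.na(pub) & (.age_rank(pub) > .age_rank(ours) | is.na(ours))
  label <- ours
  label[take_pub] <- pub[take_pub]
  prov <- ifelse(is.na(label), NA_character_,
          ifelse(take_pub, "public_db",
          ifelse(!is.na(pub) & pub == label, "merged", "pipeline")))
  data.frame(lncrna_id = names(ours), label = unname(label),
             provenance = unname(prov))
}

# ---- plain-vector internals ----------------------------------------------

# Nearest flanking coding genes (left/right on the genome axis) within a
# window. `loci` and `coding` are data.frames with chrom/start/end/strand/
# gene_id. Returns a data.frame aligned with `loci` rows.
.flanks0 <- function(loci, coding, window) {
  n <- nrow(loci)
  out <- data.frame(left_id = rep(NA_character_, n),
                    left_strand = rep(NA_character_, n),
                    right_id = rep(NA_character_, n),
                    right_strand = rep(NA_character_, n))
  if (!nrow(coding)) return(out)
  for (cc in unique(loci$chrom)) {
    ci <- which(coding$chrom == cc)
    li <- which(loci$chrom == cc)
    if (!length(ci) || !length(li)) next
    oe <- ci[order(coding$end[ci])]     # for left flanks: sorted ends
    os <- ci[order(coding$start[ci])]   # for right flanks: sorted starts
    ends <- coding$end[oe]
    starts <- coding$start[os]
    kl <- findInterval(loci$start[li] - 1L, ends)
    has_l <- kl >= 1L
    has_l[has_l] <- loci$start[li][has_l] - ends[kl[has_l]] <= window
    jl <- oe[pmax(kl, 1L)]
    out$left_id[li[has_l]] <- coding$gene_id[jl[has_l]]
    out$left_strand[li[has_l]] <- coding$strand[jl[has_l]]
    kr <- findInterval(loci$end[li], starts) + 1L
    has_r <- kr <= length(starts)
    has_r[has_r] <- starts[kr[has_r]] - loci$end[li][has_r] <= window
    jr <- os[pmin(kr, length(starts))]
    out$right_id[li[has_r]] <- coding$gene_id[jr[has_r]]
    out$right_strand[li[has_r]] <- coding$strand[jr[has_r]]
  }
  out
}

# Match a transferred locus (plain coordinates) against sink lncRNA spans.
.match0 <- function(t_chrom, t_start, t_end, t_strand, qf, sink, sink_flanks,
                    ortho) {
  cand <- which(sink$chrom == t_chrom & sink$start <= t_end &
                  sink$end >= t_start & sink$strand == t_strand)
  if (!length(cand)) return(NA_character_)
  q_l <- qf$left_id; q_r <- qf$right_id
  ok_l <- !is.na(q_l) && !is.na(ortho[q_l])
  ok_r <- !is.na(q_r) && !is.na(ortho[q_r])
  keep <- logical(length(cand))
  if (ok_l) {
    keep <- keep | (!is.na(sink_flanks$left_id[cand]) &
                      sink_flanks$left_id[cand] == ortho[[q_l]] &
                      !is.na(qf$left_strand) &
                      sink_flanks$left_strand[cand] == qf$left_strand)
  }
  if (ok_r) {
    keep <- keep | (!is.na(sink_flanks$right_id[cand]) &
                      sink_flanks$right_id[cand] == ortho[[q_r]] &
                      !is.na(qf$right_strand) &
                      sink_flanks$right_strand[cand] == qf$right_strand)
  }
  cand <- cand[keep]
  if (!length(cand)) return(NA_character_)
  ov <- pmin(sink$end[cand], t_end) - pmax(sink$start[cand], t_start) + 1L
  ids <- sink$gene_id[cand]
  ids[order(-ov, ids)][1L]
}

#' Match a transferred locus to a target-species lncRNA
#'
#' A target lncRNA matches when it (i) overlaps the transferred interval by
#' at least one base, (ii) lies on the same strand as the transfer, and
#' (iii) shares with the query lncRNA at least one neighboring one-to-one
#' protein-coding ortholog on the same relative side and strand. Ties are
#' broken by largest overlap, then smallest id.
#'
#' @param transferred `GRanges` of length 1 (strand = transfer orientation).
#' @param query_flanks One-row `data.frame` with `left_id`, `left_strand`,
#'   `right_id`, `right_strand` for the query lncRNA (`NA` when absent);
#'   see [flanking_coding_genes()].
#' @param target_lncrnas `GRanges` of target lncRNA spans with `gene_id`.
#' @param target_flanks Flanking table for `target_lncrnas` (same schema).
#' @param ortholog_map Named character vector mapping query coding gene ids
#'   to their one-to-one target orthologs.
#' @return Matching target lncRNA `gene_id`, or `NA_character_`.
#' @export
match_target_lncrna <- function(transferred, query_flanks, target_lncrnas,
                                target_flanks, ortholog_map) {
  if (is.null(transferred) || !length(target_lncrnas)) return(NA_character_)
  sink <- data.frame(chrom = as.character(seqnames(target_lncrnas)),
                     start = start(target_lncrnas),
                     end = end(target_lncrnas),
                     strand = as.character(strand(target_lncrnas)),
                     gene_id = mcols(target_lncrnas)$gene_id)
  .match0(as.character(seqnames(transferred)), start(transferred),
          end(transferred), as.character(strand(transferred)),
          query_flanks, sink, target_flanks, ortholog_map)
}

#' Nearest flanking coding genes of a set of loci
#'
#' For each locus, the nearest protein-coding gene entirely to its left and
#' to its right within `window` bp, with strands — the neighborhood used by
#' the shared-ortholog clause of the homology rule.
#'
#' @param loci `GRanges` with `gene_id`.
#' @param coding `GRanges` of coding gene spans with `gene_id`.
#' @param window Maximum flank distance in bp.
#' @return `data.frame` aligned with `loci`: `left_id`, `left_strand`,
#'   `right_id`, `right_strand` (`NA` when absent).
#' @export
flanking_coding_genes <- function(loci, coding, window = 500000L) {
  .flanks0(data.frame(chrom = as.character(seqnames(loci)),
                      start = start(loci), end = end(loci),
                      strand = as.character(strand(loci)),
                      gene_id = mcols(loci)$gene_id),
           data.frame(chrom = as.character(seqnames(coding)),
                      start = start(coding), end = end(coding),
                      strand = as.character(strand(coding)),
                      gene_id = mcols(coding)$gene_id),
           window)
}

# Spans of (optionally TE-masked) lncRNA metagenes of one species, as a
# plain data.frame. Metagenes whose masked model is empty are dropped.
# TE subtraction is done arithmetically on the flat interval table (only
# the surviving span and emptiness matter here).
.lnc_spans0 <- function(exons, tes, mask) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  mg <- .metagenes_by_gene(exons, biotype = "lncRNA")
  if (!length(mg)) return(empty)
  flat <- unlist(mg, use.names = TRUE)
  df <- data.frame(gene_id = names(flat),
                   chrom = as.character(seqnames(flat)),
                   start = start(flat), end = end(flat),
                   strand = as.character(strand(flat)))
  if (mask && length(tes)) {
    te_red <- GenomicRanges::reduce(tes, ignore.strand = TRUE)
    h <- findOverlaps(flat, te_red, ignore.strand = TRUE)
    if (length(h)) {
      qh <- queryHits(h); sh <- subjectHits(h)
      cs <- pmax(start(te_red)[sh], df$start[qh])  # clipped TE pieces,
      ce <- pmin(end(te_red)[sh], df$end[qh])      # disjoint + sorted per qh
      covered <- rep(0L, nrow(df))
      for (i in unique(qh)) {
        sel <- which(qh == i)
        s <- cs[sel]; e <- ce[sel]
        covered[i] <- sum(e - s + 1L)
        st <- df$start[i]
        for (k in seq_along(s)) {
          if (s[k] <= st) st <- max(st, e[k] + 1L) else break
        }
        en <- df$end[i]
        for (k in rev(seq_along(s))) {
          if (e[k] >= en) en <- min(en, s[k] - 1L) else break
        }
        df$start[i] <- st; df$end[i] <- en
      }
      width_left <- (end(flat) - start(flat) + 1L) - covered
      df <- df[width_left > 0L, ]
      if (!nrow(df)) return(empty)
    }
  }
  out <- data.frame(
    gene_id = sort(unique(df$gene_id)),
    chrom = as.character(tapply(df$chrom, df$gene_id, `[`, 1L)),
    start = as.integer(tapply(df$start, df$gene_id, min)),
    end = as.integer(tapply(df$end, df$gene_id, max)),
    strand = as.character(tapply(df$strand, df$gene_id, `[`, 1L)))
  rownames(out) <- NULL
  out
}

# GRanges of gene spans for one biotype from a bundle gene table.
.gene_span_gr <- function(gtab, biotype) {
  g <- gtab[gtab$biotype == biotype, ]
  GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand,
          gene_id = g$gene_id)
}

# Plain span table of one biotype from a bundle gene table.
.gene_tab0 <- function(gtab, biotype) {
  g <- gtab[gtab$biotype == biotype,
            c("gene_id", "chrom", "start", "end", "strand")]
  rownames(g) <- NULL
  g
}

# One direction of the homology analysis: lift every source span and match
# it against the sink lncRNAs. All inputs plain; returns data.frame
# (query_id, target_id).
.direction_pairs0 <- function(src_spans, src_flanks, sink_lnc, sink_flanks,
                              chains, min_match, min_blocks, ortho) {
  qid <- character(0); tid <- character(0)
  bc_cache <- lapply(chains, .chain_block_coords)
  for (i in seq_len(nrow(src_spans))) {
    r <- .lift0(chains, src_spans$chrom[i], src_spans$start[i] - 1L,
                src_spans$end[i], min_match, min_blocks, bc_cache)
    if (!r$ok) next
    qs <- src_spans$strand[i]
    tstrand <- if (r$flip) ifelse(qs == "+", "-", "+") else qs
    qf <- list(left_id = src_flanks$left_id[i],
               left_strand = src_flanks$left_strand[i],
               right_id = src_flanks$right_id[i],
               right_strand = src_flanks$right_strand[i])
    hit <- .match0(r$t_chrom, r$t0s + 1L, r$t0e, tstrand, qf,
                   sink_lnc, sink_flanks, ortho)
    if (!is.na(hit)) { qid <- c(qid, src_spans$gene_id[i]); tid <- c(tid, hit) }
  }
  data.frame(query_id = qid, target_id = tid)
}

#' Collect per-species homology evidence for every query lncRNA
#'
#' Runs both lift directions for one pass (TE-masked or TE-retained)
#' against every target species of a synthetic or assembled bundle.
#'
#' @param bundle A bundle with `annotations`, `genes`, `tes`, `orthologs`,
#'   `chains` (see [simulate_bundle()]).
#' @param pass `"te_masked"` or `"te_retained"`.
#' @param min_match_deep,min_blocks_deep Lift thresholds for the deepest
#'   (bird-depth, 300 Mya) comparison; defaults 0.01/0.01.
#' @param min_match,min_blocks Lift thresholds for the mammalian-depth
#'   comparisons; defaults 0.10/0.01.
#' @param neighbor_window_bp Window for the neighboring-ortholog rule.
#' @return `data.frame` with one row per (lncRNA, species): `lncrna_id`,
#'   `species`, `pass`, `forward_hit`, `reciprocal` (logical),
#'   `nonreciprocal` (logical: signal in exactly one direction).
#' @export
homology_evidence <- function(bundle, pass = c("te_masked", "te_retained"),
                              min_match_deep = 0.01, min_blocks_deep = 0.01,
                              min_match = 0.10, min_blocks = 0.01,
                              neighbor_window_bp = 500000L) {
  pass <- match.arg(pass)
  mask <- pass == "te_masked"
  # per-species caches: source spans (masked per pass), sink spans
  # (annotated gene spans), coding spans, flank tables
  sps <- c("Q", bundle$species$name)
  src_spans <- list(); sink_lnc <- list(); coding <- list()
  src_flanks <- list(); sink_flanks <- list()
  for (sp in sps) {
    src_spans[[sp]] <- .lnc_spans0(bundle$annotations[[sp]],
                                   bundle$tes[[sp]], mask)
    sink_lnc[[sp]] <- .gene_tab0(bundle$genes[[sp]], "lncRNA")
    coding[[sp]] <- .gene_tab0(bundle$genes[[sp]], "protein_coding")
    src_flanks[[sp]] <- .flanks0(src_spans[[sp]], coding[[sp]],
                                 neighbor_window_bp)
    sink_flanks[[sp]] <- .flanks0(sink_lnc[[sp]], coding[[sp]],
                                  neighbor_window_bp)
  }
  out <- list()
  for (sp in bundle$species$name) {
    depth <- bundle$species$depth[bundle$species$name == sp]
    mm <- if (depth >= 300) min_match_deep else min_match
    mb <- if (depth >= 300) min_blocks_deep else min_blocks
    om <- bundle$orthologs[bundle$orthologs$species == sp, ]
    ortho_f <- setNames(om$target_gene, om$query_gene)
    ortho_r <- setNames(om$query_gene, om$target_gene)
    fwd <- .direction_pairs0(src_spans$Q, src_flanks$Q, sink_lnc[[sp]],
                             sink_flanks[[sp]],
                             bundle$chains[[paste0("Q_to_", sp)]],
                             mm, mb, ortho_f)
    rev <- .direction_pairs0(src_spans[[sp]], src_flanks[[sp]], sink_lnc$Q,
                             sink_flanks$Q,
                             bundle$chains[[paste0(sp, "_to_Q")]],
                             mm, mb, ortho_r)
    # orient reverse pairs as (query lncRNA, target lncRNA)
    rev_o <- data.frame(query_id = rev$target_id, target_id = rev$query_id)
    recip <- reciprocal_filter(fwd, rev_o)
    ids <- sink_lnc$Q$gene_id
    fh <- fwd$target_id[match(ids, fwd$query_id)]
    is_recip <- paste(ids, fh) %in% paste(recip$query_id, recip$target_id)
    named_rev <- ids %in% rev_o$query_id
    nonrecip <- (!is_recip) & (!is.na(fh) | named_rev)
    out[[sp]] <- data.frame(lncrna_id = ids, species = sp, pass = pass,
                            forward_hit = fh, reciprocal = is_recip,
                            nonreciprocal = nonrecip)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign a minimal evolutionary age from evidence and public annotations
#'
#' @param evidence `data.frame` from [homology_evidence()], both passes
#'   bound together.
#' @param species_depths Named numeric vector: species name to divergence
#'   depth in Mya.
#' @param public Named character vector of public synteny labels (may be
#'   empty).
#' @return `data.frame` with `lncrna_id`, `label` (one of `300`, `90`,
#'   `25`, `apes`, `human_specific`, `uncertain`), `provenance`.
#' @export
assign_ma <- function(evidence, species_depths, public = character(0)) {
  ids <- unique(evidence$lncrna_id)
  draft_of_pass <- function(p) {
    ev <- evidence[evidence$pass == p & evidence$reciprocal, ]
    d <- tapply(species_depths[ev$species], ev$lncrna_id, max)
    lab <- as.character(d)[match(ids, names(d))]
    setNames(lab, ids)
  }
  passes <- unique(evidence$pass)
  draft <- draft_of_pass(passes[1L])
  if (length(passes) > 1L) {
    for (p in passes[-1L]) draft <- merge_passes(draft, draft_of_pass(p))
  }
  merged <- merge_public(draft, public)
  nonrec_ids <- unique(evidence$lncrna_id[evidence$nonreciprocal])
  nonrec <- ids %in% nonrec_ids
  none <- is.na(merged$label)
  merged$label[none & nonrec] <- "uncertain"
  merged$label[none & !nonrec] <- "human_specific"
  merged$provenance[none] <- "pipeline"
  merged
}

#' Run the full MA classification on a bundle
#'
#' Both passes (TE-masked and TE-retained), reciprocal filtering, pass
#' merging, public-annotation merging, and final label assignment.
#'
#' @inheritParams homology_evidence
#' @param public Named character vector of public synteny labels.
#' @return List with `assignments` (`data.frame`: `lncrna_id`, `label`,
#'   `provenance`) and `evidence` (the per-species table).
#' @export
annotate_ages <- function(bundle, public = character(0),
                          min_match_deep = 0.01, min_blocks_deep = 0.01,
                          min_match = 0.10, min_blocks = 0.01,
                          neighbor_window_bp = 500000L) {
  ev <- rbind(
    homology_evidence(bundle, "te_masked", min_match_deep, min_blocks_deep,
                      min_match, min_blocks, neighbor_window_bp),
    homology_evidence(bundle, "te_retained", min_match_deep, min_blocks_deep,
                      min_match, min_blocks, neighbor_window_bp))
  depths <- setNames(bundle$species$depth, bundle$species$name)
  list(assignments = assign_ma(ev, depths, public), evidence = ev)
}

#' Classify a lncRNA by its position relative to protein-coding genes
#'
#' Precedence: `antisense` (exonic overlap with a coding gene on the
#' opposite strand), `overlapping` (exonic overlap, same strand),
#' `intronic` (fully inside a coding gene's span with no exonic overlap),
#' `intergenic_proximal` (no overlap, nearest coding gene within
#' `proximal_window_bp`), else `intergenic_distal`.
#'
#' @param lnc_metagene `GRanges` of the lncRNA's metagene intervals.
#' @param coding_exons `GRanges` of coding-gene exons with `gene_id`.
#' @param coding_spans `GRanges` of coding-gene spans with `gene_id`.
#' @param proximal_window_bp Window for the proximal/distal split.
#' @return One of the five positional class labels.
#' @export
classify_positional_type <- function(lnc_metagene, coding_exons, coding_spans,
                                     proximal_window_bp = 5000L) {
  stopifnot(is(lnc_metagene, "GRanges"), length(lnc_metagene) >= 1L)
  ls <- as.character(strand(lnc_metagene))[1L]
  hits <- findOverlaps(lnc_metagene, coding_exons, ignore.strand = TRUE)
  if (length(hits)) {
    es <- as.character(strand(coding_exons))[subjectHits(hits)]
    if (any(es != ls)) return("antisense")
    return("overlapping")
  }
  span <- range(lnc_metagene, ignore.strand = TRUE)
  within <- findOverlaps(span, coding_spans, type = "within",
                         ignore.strand = TRUE)
  if (length(within)) return("intronic")
  d <- closest_gene(span, coding_spans, max_distance_bp = proximal_window_bp)
  if (!is.na(d$subject_idx[1L])) return("intergenic_proximal")
  "intergenic_distal"
}
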