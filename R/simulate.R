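# Synthetic four-plus-one-species dataset with planted ground truth.
#
# The generator emulates the inputs of the MA-classification pipeline:
# per-species gene annotations with one-to-one protein-coding orthologs,
# planted lncRNAs of known minimal age, TE annotations, pairwise alignment
# chains in both directions, an expression matrix with an age-dependent
# gradient, cell-cluster and compartment DE tables, a coding-potential call
# table, and promoter TF peaks. A single linear coordinate system per
# chromosome is used (no rearrangements): true homologs keep strand and
# gene order, so synteny is preserved by construction. Chains encode
# identity-like alignments with small indels (<= 10 bp) between aligned
# units so minMatch/minBlocks thresholds are exercised.

.SPECIES_DEPTH <- c(T25 = 25, T90 = 90, T300 = 300)
.TE_CLASS <- c(Alu = "SINE", MIR = "SINE", L1 = "LINE", L2 = "LINE",
               CR1 = "LINE", `ERVL-MaLR` = "LTR", DNA = "DNA",
               other = "other")

#' Build and validate a simulation configuration
#'
#' Defaults define the study conditions of the synthetic bundle: four age
#' groups of planted lncRNAs (300/90/25 Mya and human-specific), a
#' protein-coding ortholog scaffold shared by all species, and a monotone
#' expression gradient where older lncRNAs are more highly expressed.
#'
#' @param seed Root seed; all stage-level randomness is derived from it via
#'   named substreams.
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param n_coding_genes Number of protein-coding scaffold genes (shared
#'   one-to-one across species).
#' @param n_lncrnas_per_age Named counts for ages `"300"`, `"90"`, `"25"`,
#'   `"human_specific"`.
#' @param te_family_weights Named sampling weights over TE families.
#' @param te_density_per_mb Expected TE insertions per megabase.
#' @param homology_dropout Probability that a truly conserved lncRNA loses
#'   its chain coverage in one direction (independently per direction and
#'   species); creates nonreciprocal, hence "uncertain", cases.
#' @param expression_design `data.frame` with columns `window`, `region`,
#'   `n_samples` (one row per developmental window/region pair).
#' @param mean_log_expression_by_age Named mean log2 expression per age
#'   group; must decrease with youth.
#' @param mean_log_expression_coding Mean log2 expression of coding genes.
#' @param dispersion SD of per-gene log2 expression around its group mean.
#' @param calculator_error_rate Probability that each coding-potential call
#'   (and the ORF flag) is flipped.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1500000L,
                       n_coding_genes = 60L,
                       n_lncrnas_per_age = c(`300` = 10L, `90` = 10L,
                                             `25` = 10L, human_specific = 10L),
                       te_family_weights = c(Alu = 0.30, L1 = 0.20, L2 = 0.10,
                                             MIR = 0.10, `ERVL-MaLR` = 0.10,
                                             CR1 = 0.05, DNA = 0.10,
                                             other = 0.05),
                       te_density_per_mb = 30,
                       homology_dropout = 0,
                       expression_design = data.frame(
                         window = c("W1", "W1", "W2", "W2"),
                         region = c("FC", "OC", "FC", "OC"),
                         n_samples = 3L),
                       mean_log_expression_by_age = c(`300` = 5, `90` = 4,
                                                      `25` = 3,
                                                      human_specific = 2),
                       mean_log_expression_coding = 5.5,
                       dispersion = 0.6,
                       calculator_error_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              n_coding_genes = as.integer(n_coding_genes),
              n_lncrnas_per_age = n_lncrnas_per_age,
              te_family_weights = te_family_weights,
              te_density_per_mb = te_density_per_mb,
              homology_dropout = homology_dropout,
              expression_design = expression_design,
              mean_log_expression_by_age = mean_log_expression_by_age,
              mean_log_expression_coding = mean_log_expression_coding,
              dispersion = dispersion,
              calculator_error_rate = calculator_error_rate)
  ages <- c("300", "90", "25", "human_specific")
  stopifnot(cfg$n_chromosomes > 0L, cfg$chrom_length_bp > 0L,
            cfg$n_coding_genes > 0L,
            all(ages %in% names(cfg$n_lncrnas_per_age)),
            all(cfg$n_lncrnas_per_age >= 0),
            all(cfg$te_family_weights >= 0),
            all(names(cfg$te_family_weights) %in% names(.TE_CLASS)),
            cfg$homology_dropout >= 0, cfg$homology_dropout <= 1,
            nrow(cfg$expression_design) > 0L,
            all(cfg$expression_design$n_samples > 0L),
            all(ages %in% names(cfg$mean_log_expression_by_age)),
            cfg$dispersion > 0,
            cfg$calculator_error_rate >= 0, cfg$calculator_error_rate <= 1)
  n_lnc <- sum(cfg$n_lncrnas_per_age)
  if (cfg$n_coding_genes < n_lnc + cfg$n_chromosomes) {
    stop("sizing error: need at least one more coding gene than lncRNAs per ",
         "chromosome so every lncRNA has coding flanks")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Draw exon/intron structures for one gene; returns list(exon_w, intron_w).
.draw_structure <- function(biotype) {
  n_ex <- if (biotype == "protein_coding") sample(2:5, 1L) else sample(1:3, 1L)
  list(exon_w = sample(100:400, n_ex, replace = TRUE),
       intron_w = if (n_ex > 1L) sample(200:800, n_ex - 1L, replace = TRUE)
                  else integer(0))
}

#' Simulate the multi-species genome annotations
#'
#' Lays out a protein-coding ortholog scaffold with interleaved lncRNAs on
#' each chromosome of the query species `Q`, then replays the same gene
#' order in targets `T25`, `T90`, `T300` with small per-unit coordinate
#' indels. A lncRNA of true age `A` is annotated in every target whose
#' divergence depth is `<= A` and absent from deeper targets; coding genes
#' are present everywhere and define the one-to-one ortholog map.
#'
#' @param config A [sim_config()].
#' @return A bundle list with `annotations` (per-species exon `GRanges`),
#'   `genes` (per-species gene tables), `tes`, `orthologs`, `truth`,
#'   `layout` (aligned units used to emit chains), `chrom_sizes`, `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream_seed(config$seed, "genomes"), {
    ages <- rep(names(config$n_lncrnas_per_age),
                times = config$n_lncrnas_per_age)
    n_lnc <- length(ages)
    n_pc <- config$n_coding_genes
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))

    # global gene table: ids, biotype, age, structure, strand
    gene <- data.frame(
      gene_id = c(sprintf("pc%04d", seq_len(n_pc)),
                  sprintf("lnc%04d", seq_len(n_lnc))),
      biotype = c(rep("protein_coding", n_pc), rep("lncRNA", n_lnc)),
      age = c(rep(NA_character_, n_pc), sample(ages)),
      strand = sample(c("+", "-"), n_pc + n_lnc, replace = TRUE))
    structures <- lapply(gene$biotype, .draw_structure)
    gene$span <- vapply(structures, function(s) sum(s$exon_w) + sum(s$intron_w),
                        numeric(1))

    # slot order per chromosome: coding genes round-robin, each lncRNA
    # inserted after a distinct non-terminal coding gene of its chromosome
    pc_chrom <- rep(chroms, length.out = n_pc)
    lnc_chrom <- rep(chroms, length.out = n_lnc)
    slot_order <- unlist(lapply(seq_along(chroms), function(ci) {
      pcs <- which(gene$biotype == "protein_coding")[pc_chrom == chroms[ci]]
      lncs <- which(gene$biotype == "lncRNA")[lnc_chrom == chroms[ci]]
      if (length(lncs) > length(pcs) - 1L) {
        stop("sizing error: too many lncRNAs for the coding scaffold of ",
             chroms[ci])
      }
      after <- sort(sample(length(pcs) - 1L, length(lncs)))
      out <- integer(0)
      li <- 1L
      for (k in seq_along(pcs)) {
        out <- c(out, pcs[k])
        while (li <= length(lncs) && after[li] == k) {
          out <- c(out, lncs[li]); li <- li + 1L
        }
      }
      out
    }), use.names = FALSE)
    gene$chrom <- NA_character_
    gene$chrom[slot_order] <- rep(chroms,
                                  times = vapply(chroms, function(cc) {
                                    sum(pc_chrom == cc) + sum(lnc_chrom == cc)
                                  }, integer(1)))

    # Q layout: walk slots, drop genes with flanking gap; record aligned units
    q_start <- numeric(nrow(gene))
    layout_rows <- list()
    for (ci in seq_along(chroms)) {
      idx <- slot_order[gene$chrom[slot_order] == chroms[ci]]
      pos <- 1001L
      for (g in idx) {
        gap <- sample(3000:8000, 1L)
        unit_start <- pos
        q_start[g] <- pos + sample(200:800, 1L)
        pos <- as.integer(q_start[g] + gene$span[g] + gap)
        if (pos > config$chrom_length_bp - 1000L) {
          stop("sizing error: chromosome overflow on ", chroms[ci],
               " (too many genes for chrom_length_bp)")
        }
        # units leave a 15 bp unaligned sliver between them so per-species
        # indels (<= 10 bp) never make a chain gap negative
        layout_rows[[length(layout_rows) + 1L]] <-
          data.frame(chrom = chroms[ci], gene_idx = g,
                     q_start = unit_start, q_end = pos - 15L)
      }
    }
    units <- do.call(rbind, layout_rows)
    gene$q_start <- as.integer(q_start)
    gene$q_end <- as.integer(q_start + gene$span - 1L)

    # isoforms: every gene has one full isoform; half get a second isoform
    # missing its last exon (when multi-exonic) to exercise metagene merging
    species <- c("Q", names(.SPECIES_DEPTH))
    second_iso <- runif(nrow(gene)) < 0.5
    # flat exon template (gene index, isoform, exon offset/width), shared by
    # all species; per-species coordinates are added vectorized below
    tg <- list(); ti <- list(); tr <- list(); tw <- list()
    for (g in seq_len(nrow(gene))) {
      st <- structures[[g]]
      n_ex <- length(st$exon_w)
      rel <- cumsum(c(0L, head(st$exon_w, -1L) + st$intron_w))
      two <- second_iso[g] && n_ex > 1L
      ks <- c(seq_len(n_ex), if (two) seq_len(n_ex - 1L))
      tg[[g]] <- rep.int(g, length(ks))
      ti[[g]] <- rep.int(seq_len(1L + two), c(n_ex, if (two) n_ex - 1L))
      tr[[g]] <- rel[ks]
      tw[[g]] <- st$exon_w[ks]
    }
    tmpl <- data.frame(gi = unlist(tg), iso = unlist(ti),
                       rel = as.integer(unlist(tr)), w = unlist(tw))

    # per-target per-unit indels give each species its own coordinates
    layout <- list()
    offsets <- list(Q = NULL)
    for (sp in names(.SPECIES_DEPTH)) {
      lay <- units
      lay$t_start <- NA_integer_
      for (ci in seq_along(chroms)) {
        sel <- which(lay$chrom == chroms[ci])
        lead <- sample(0:1000, 1L)
        ds <- sample(0:10, length(sel), replace = TRUE)
        dt <- sample(0:10, length(sel), replace = TRUE)
        drift <- cumsum(c(0L, head(dt - ds, -1L)))
        lay$t_start[sel] <- lay$q_start[sel] + lead + drift
      }
      layout[[sp]] <- lay
      off <- integer(nrow(gene))
      off[lay$gene_idx] <- lay$t_start - lay$q_start
      offsets[[sp]] <- off
    }

    depth_of_age <- function(a) {
      d <- suppressWarnings(as.numeric(a))
      ifelse(is.na(a), -1, ifelse(a == "human_specific", 0, d))
    }
    annotations <- list(); genes <- list(); tes <- list()
    ortho_rows <- list(); homolog_rows <- list()
    genome_mb <- config$n_chromosomes * config$chrom_length_bp / 1e6
    n_te <- max(1L, round(config$te_density_per_mb * genome_mb))
    for (sp in species) {
      present <- if (sp == "Q") rep(TRUE, nrow(gene)) else {
        gene$biotype == "protein_coding" |
          depth_of_age(gene$age) >= .SPECIES_DEPTH[[sp]]
      }
      off <- if (sp == "Q") integer(nrow(gene)) else offsets[[sp]]
      gtab <- gene[present, c("gene_id", "biotype", "age", "strand", "chrom")]
      gtab$gene_id <- paste(sp, gtab$gene_id, sep = ".")
      gtab$start <- gene$q_start[present] + off[present]
      gtab$end <- gene$q_end[present] + off[present]
      genes[[sp]] <- gtab[order(gtab$chrom, gtab$start), ]
      rownames(genes[[sp]]) <- NULL

      # exon records
      tt <- tmpl[present[tmpl$gi], ]
      starts <- as.integer(gene$q_start[tt$gi] + off[tt$gi] + tt$rel)
      gr <- GRanges(gene$chrom[tt$gi], IRanges(starts, width = tt$w),
                    strand = gene$strand[tt$gi], type = "exon",
                    transcript_id = sprintf("%s.%s.t%d", sp,
                                            gene$gene_id[tt$gi], tt$iso),
                    gene_id = paste(sp, gene$gene_id[tt$gi], sep = "."),
                    gene_biotype = gene$biotype[tt$gi])
      annotations[[sp]] <- sort(gr, ignore.strand = TRUE)

      # TE insertions (uniform; family by configured weights)
      fam <- sample(names(config$te_family_weights), n_te, replace = TRUE,
                    prob = config$te_family_weights)
      te_w <- sample(150:600, n_te, replace = TRUE)
      te_chr <- sample(chroms, n_te, replace = TRUE)
      te_s <- floor(runif(n_te, 1, config$chrom_length_bp - te_w))
      tes[[sp]] <- sort(GRanges(te_chr, IRanges(as.integer(te_s),
                                                width = te_w),
                                strand = sample(c("+", "-"), n_te, TRUE),
                                name = fam,
                                te_class = unname(.TE_CLASS[fam])),
                        ignore.strand = TRUE)

      if (sp != "Q") {
        pcs <- gene$biotype == "protein_coding"
        ortho_rows[[sp]] <- data.frame(
          query_gene = paste("Q", gene$gene_id[pcs], sep = "."),
          target_gene = paste(sp, gene$gene_id[pcs], sep = "."),
          species = sp)
        hl <- present & gene$biotype == "lncRNA"
        if (any(hl)) {
          homolog_rows[[sp]] <- data.frame(
            lncrna_id = paste("Q", gene$gene_id[hl], sep = "."),
            species = sp,
            target_id = paste(sp, gene$gene_id[hl], sep = "."))
        }
      }
    }

    lnc_sel <- gene$biotype == "lncRNA"
    truth <- list(
      true_age = setNames(gene$age[lnc_sel],
                          paste("Q", gene$gene_id[lnc_sel], sep = ".")),
      homologs = if (length(homolog_rows)) do.call(rbind, homolog_rows)
                 else data.frame(lncrna_id = character(0),
                                 species = character(0),
                                 target_id = character(0)))
    rownames(truth$homologs) <- NULL

    list(config = config,
         species = data.frame(name = names(.SPECIES_DEPTH),
                              depth = unname(.SPECIES_DEPTH)),
         annotations = annotations, genes = genes, tes = tes,
         orthologs = do.call(rbind, ortho_rows),
         truth = truth, layout = layout,
         chrom_sizes = setNames(rep(config$chrom_length_bp, length(chroms)),
                                chroms))
  })
}

# Remove [cut_start, cut_end] (1-based closed, source coords) from a block
# table data.frame(src_start, src_end, tgt_start) -- equal-length aligned
# pieces, so target coordinates follow source offsets directly.
.cut_blocks <- function(blocks, cut_start, cut_end) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$src_end < cut_start || b$src_start > cut_end) {
      out[[length(out) + 1L]] <- b
      next
    }
    if (b$src_start < cut_start) {
      out[[length(out) + 1L]] <-
        data.frame(src_start = b$src_start, src_end = cut_start - 1L,
                   tgt_start = b$tgt_start)
    }
    if (b$src_end > cut_end) {
      out[[length(out) + 1L]] <-
        data.frame(src_start = cut_end + 1L, src_end = b$src_end,
                   tgt_start = b$tgt_start + (cut_end + 1L - b$src_start))
    }
  }
  if (!length(out)) return(blocks[0, ])
  do.call(rbind, out)
}

# Assemble chain records (one per chromosome) from a block table.
.blocks_to_chains <- function(blocks, src_sizes, tgt_sizes, id_prefix) {
  chains <- list()
  for (cc in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == cc, ]
    b <- b[order(b$src_start), ]
    if (!nrow(b)) next
    size <- b$src_end - b$src_start + 1L
    ds <- c(b$src_start[-1L] - (b$src_start[-nrow(b)] + size[-nrow(b)]), 0L)
    dt <- c(b$tgt_start[-1L] - (b$tgt_start[-nrow(b)] + size[-nrow(b)]), 0L)
    if (any(ds < 0L) || any(dt < 0L)) stop("non-monotone block table")
    ch <- list(chain_id = paste0(id_prefix, "_", cc),
               score = sum(size),
               source_chrom = cc, source_size = unname(src_sizes[cc]),
               source_strand = "+",
               source_start = b$src_start[1L] - 1L,
               source_end = b$src_start[nrow(b)] - 1L + size[nrow(b)] +
                 sum(ds[-length(ds)]),
               target_chrom = cc, target_size = unname(tgt_sizes[cc]),
               target_strand = "+",
               target_start = b$tgt_start[1L] - 1L,
               target_end = b$tgt_start[nrow(b)] - 1L + size[nrow(b)] +
                 sum(dt[-length(dt)]),
               blocks = data.frame(size = size, dsource = ds, dtarget = dt))
    # spans must equal the block sums exactly
    ch$source_end <- ch$source_start + sum(size + ds)
    ch$target_end <- ch$target_start + sum(size + dt)
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Simulate pairwise alignment chains in both directions
#'
#' Emits UCSC-style chains `Q -> Tk` and `Tk -> Q` for every target species,
#' covering all aligned units. With `homology_dropout = d`, each truly
#' conserved lncRNA loses the chain coverage over its locus in the forward
#' direction with probability `d` and, independently, in the reverse
#' direction with probability `d` — the source of nonreciprocal (hence
#' "uncertain") classifications downstream.
#'
#' @param bundle Output of [simulate_genomes()].
#' @return The bundle with `chains` (named `"Q_to_T25"`, `"T25_to_Q"`, ...)
#'   and `dropout_log` (`data.frame`: `lncrna_id`, `species`, `direction`).
#' @export
simulate_chains <- function(bundle) {
  config <- bundle$config
  .with_seed(.substream_seed(config$seed, "chains"), {
    chains <- list()
    drop_rows <- list()
    hom <- bundle$truth$homologs
    for (sp in names(.SPECIES_DEPTH)) {
      lay <- bundle$layout[[sp]]
      size <- lay$q_end - lay$q_start  # unit length (half-open widths)
      fwd <- data.frame(chrom = lay$chrom, src_start = lay$q_start,
                        src_end = lay$q_start + size - 1L,
                        tgt_start = lay$t_start)
      rev <- data.frame(chrom = lay$chrom, src_start = lay$t_start,
                        src_end = lay$t_start + size - 1L,
                        tgt_start = lay$q_start)
      hl <- hom[hom$species == sp, ]
      fwd_cuts <- list(); rev_cuts <- list()
      if (nrow(hl)) {
        gq <- bundle$genes$Q
        gt <- bundle$genes[[sp]]
        for (k in seq_len(nrow(hl))) {
          if (runif(1) < config$homology_dropout) {  # forward loss
            row <- gq[gq$gene_id == hl$lncrna_id[k], ]
            fwd_cuts[[length(fwd_cuts) + 1L]] <-
              list(chrom = row$chrom, lo = row$start - 50L, hi = row$end + 50L)
            drop_rows[[length(drop_rows) + 1L]] <-
              data.frame(lncrna_id = hl$lncrna_id[k], species = sp,
                         direction = "forward")
          }
          if (runif(1) < config$homology_dropout) {  # reverse loss
            row <- gt[gt$gene_id == hl$target_id[k], ]
            rev_cuts[[length(rev_cuts) + 1L]] <-
              list(chrom = row$chrom, lo = row$start - 50L, hi = row$end + 50L)
            drop_rows[[length(drop_rows) + 1L]] <-
              data.frame(lncrna_id = hl$lncrna_id[k], species = sp,
                         direction = "reverse")
          }
        }
      }
      apply_cuts <- function(blocks, cuts) {
        for (cut in cuts) {
          sel <- blocks$chrom == cut$chrom
          kept <- .cut_blocks(blocks[sel, c("src_start", "src_end",
                                            "tgt_start")], cut$lo, cut$hi)
          blocks <- rbind(
            blocks[!sel, ],
            if (nrow(kept)) cbind(chrom = cut$chrom, kept)
            else blocks[0, ])
        }
        blocks
      }
      fwd <- apply_cuts(fwd, fwd_cuts)
      rev <- apply_cuts(rev, rev_cuts)
      chains[[paste0("Q_to_", sp)]] <-
        .blocks_to_chains(fwd, bundle$chrom_sizes, bundle$chrom_sizes,
                          paste0("Qto", sp))
      chains[[paste0(sp, "_to_Q")]] <-
        .blocks_to_chains(rev, bundle$chrom_sizes, bundle$chrom_sizes,
                          paste0(sp, "toQ"))
    }
    bundle$chains <- chains
    bundle$dropout_log <- if (length(drop_rows)) do.call(rbind, drop_rows)
                          else data.frame(lncrna_id = character(0),
                                          species = character(0),
                                          direction = character(0))
    bundle
  })
}

# Exon-union (metagene) length of every gene in kb, from an exon GRanges.
.gene_lengths_kb <- function(exons) {
  by_gene <- split(exons, mcols(exons)$gene_id)
  vapply(by_gene, function(g) sum(width(GenomicRanges::reduce(g))),
         numeric(1)) / 1000
}

#' Simulate expression, DE tables, coding calls, and TF peaks
#'
#' Counts follow a log-normal-by-age gene mean with Poisson sampling so the
#' planted monotone expression gradient (older lncRNAs expressed more
#' highly) is recoverable from TPM. Cell-cluster DE tables plant known
#' per-gene cell-type specificity; the coding-call table flips each true
#' call with `calculator_error_rate`; TF peaks are placed over promoters
#' with category-dependent rates plus a uniform genomic background.
#'
#' @param config A [sim_config()] (normally `bundle$config`).
#' @param bundle Output of [simulate_genomes()].
#' @return The bundle extended with `expression` (`counts`, `lengths_kb`,
#'   `metadata`), `de_clusters`, `de_compartments`, `coding_calls`,
#'   `tf_peaks`, and `truth$gene_specificity`.
#' @export
simulate_expression <- function(config, bundle) {
  gq <- bundle$genes$Q
  exons <- bundle$annotations$Q
  .with_seed(.substream_seed(config$seed, "expression"), {
    lengths_kb <- .gene_lengths_kb(exons)[gq$gene_id]
    mu_log2 <- ifelse(gq$biotype == "protein_coding",
                      config$mean_log_expression_coding,
                      config$mean_log_expression_by_age[gq$age])
    lam <- 2^rnorm(nrow(gq), mean = mu_log2, sd = config$dispersion)
    des <- config$expression_design
    meta <- do.call(rbind, lapply(seq_len(nrow(des)), function(i) {
      data.frame(sample = sprintf("s_%s_%s_%d", des$window[i], des$region[i],
                                  seq_len(des$n_samples[i])),
                 window = des$window[i], region = des$region[i])
    }))
    libfac <- runif(nrow(meta), 0.8, 1.2)
    counts <- vapply(seq_len(nrow(meta)), function(s) {
      rpois(nrow(gq), lam * lengths_kb * libfac[s])
    }, numeric(nrow(gq)))
    dimnames(counts) <- list(gq$gene_id, meta$sample)

    bundle$expression <- list(counts = counts,
                              lengths_kb = setNames(lengths_kb, gq$gene_id),
                              metadata = meta)

    # --- cell-cluster DE tables with planted specificity ------------------
    clusters <- c("aRGC", "oRGC", "IPC", "GlutN", "InhMGE", "CajalRetzius")
    age_rank <- .age_rank(gq$age)  # 0 for coding genes
    k_spec <- integer(nrow(gq))
    for (i in seq_len(nrow(gq))) {
      if (runif(1) < 0.3) next  # not a marker anywhere
      w <- if (gq$biotype[i] == "protein_coding") rep(1, 6)
           else (seq_len(6))^(ifelse(age_rank[i] >= 4, 1, -1))
      k_spec[i] <- sample(1:6, 1L, prob = w / sum(w))
    }
    assign_cl <- lapply(k_spec, function(k) {
      if (k == 0L) character(0) else sample(clusters, k)
    })
    de_clusters <- lapply(setNames(clusters, clusters), function(cl) {
      sel <- vapply(assign_cl, function(cc) cl %in% cc, logical(1))
      data.frame(gene_id = gq$gene_id[sel],
                 log2fc = abs(rnorm(sum(sel), 1, 0.3)),
                 fdr = runif(sum(sel), 0, 0.049))
    })
    bundle$de_clusters <- de_clusters
    bundle$truth$gene_specificity <- setNames(k_spec, gq$gene_id)

    # --- compartment DE tables (nuclear enrichment of lncRNAs) ------------
    p_nuc <- ifelse(gq$biotype == "lncRNA", 0.5, 0.15)
    p_cyt <- ifelse(gq$biotype == "lncRNA", 0.1, 0.25)
    bundle$de_compartments <- list(
      nuclear = data.frame(gene_id = gq$gene_id[runif(nrow(gq)) < p_nuc]),
      cytoplasmic = data.frame(gene_id = gq$gene_id[runif(nrow(gq)) < p_cyt]))
    bundle
  }) -> bundle

  # --- coding-potential call table (own substream) ------------------------
  bundle <- .with_seed(.substream_seed(config$seed, "calls"), {
    tx <- unique(data.frame(transcript_id = mcols(exons)$transcript_id,
                            gene_id = mcols(exons)$gene_id,
                            biotype = mcols(exons)$gene_biotype))
    coding <- tx$biotype == "protein_coding"
    flip <- function(x) xor(x, runif(length(x)) < config$calculator_error_rate)
    lnc_loci <- unique(tx$gene_id[!coding])
    ref_lnc <- sample(lnc_loci, size = floor(0.2 * length(lnc_loci)))
    calls <- data.frame(
      transcript_id = tx$transcript_id, gene_id = tx$gene_id,
      cpc_coding = flip(coding), cpat_coding = flip(coding),
      feelnc_coding = flip(coding), orf_found = flip(coding),
      ref_biotype = ifelse(tx$gene_id %in% ref_lnc, "lncRNA", NA_character_))
    bundle$coding_calls <- calls
    bundle
  })

  # --- TF peaks over promoters with category-dependent rates --------------
  .with_seed(.substream_seed(config$seed, "peaks"), {
    tfs <- sprintf("TF%02d", 1:12)
    gq <- bundle$genes$Q
    prom <- extract_promoters(bundle$annotations$Q, upstream_bp = 1000L,
                              downstream_bp = 500L,
                              chrom_sizes = bundle$chrom_sizes)
    prom <- prom[match(gq$gene_id, mcols(prom)$gene_id)]
    rate <- ifelse(gq$biotype == "protein_coding", 0.30,
                   c(`300` = 0.25, `90` = 0.20, `25` = 0.15,
                     human_specific = 0.10)[gq$age])
    peak_rows <- list()
    for (tf in tfs) {
      r <- if (tf == "TF01") pmin(1, rate * 2.5) else rate
      hit <- which(runif(length(prom)) < r)
      if (length(hit)) {
        ctr <- (start(prom)[hit] + end(prom)[hit]) %/% 2L
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          chrom = as.character(seqnames(prom))[hit],
          start = pmax(1L, ctr - 100L), end = ctr + 99L, name = tf)
      }
      # uniform background peaks: 2 per Mb per TF
      nbg <- max(1L, round(2 * sum(bundle$chrom_sizes) / 1e6))
      bg_chr <- sample(names(bundle$chrom_sizes), nbg, replace = TRUE)
      bg_s <- floor(runif(nbg, 1, bundle$chrom_sizes[bg_chr] - 200))
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = bg_chr, start = as.integer(bg_s),
        end = as.integer(bg_s + 199L), name = tf)
    }
    pk <- do.call(rbind, peak_rows)
    bundle$tf_peaks <- sort(GRanges(pk$chrom, IRanges(pk$start, pk$end),
                                    strand = "*", name = pk$name),
                            ignore.strand = TRUE)
    bundle
  })
}

#' Simulate a complete bundle (genomes, chains, expression)
#'
#' @param config A [sim_config()].
#' @return Complete in-memory bundle.
#' @export
simulate_bundle <- function(config = sim_config()) {
  bundle <- simulate_genomes(config)
  bundle <- simulate_chains(bundle)
  simulate_expression(config, bundle)
}

#' Write a simulated bundle to disk
#'
#' Emits per-species GTF and TE BED files, ortholog and coding-call TSVs,
#' chain files for both directions of every species pair, the count matrix
#' with sample metadata, DE tables, and the TF peak BED. All writers are
#' deterministic: identical bundles give byte-identical files.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(bundle$annotations)) {
    write_gtf(bundle$annotations[[sp]], file.path(dir, paste0(sp, ".gtf")))
    write_bed(bundle$tes[[sp]], file.path(dir, paste0(sp, ".te.bed")))
  }
  write.table(bundle$orthologs, file.path(dir, "orthologs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$chains)) {
    write_chain(bundle$chains[[nm]], file.path(dir, paste0(nm, ".chain")))
  }
  if (!is.null(bundle$expression)) {
    write.table(data.frame(gene_id = rownames(bundle$expression$counts),
                           bundle$expression$counts, check.names = FALSE),
                file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bundle$expression$metadata, file.path(dir, "metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$coding_calls)) {
    write.table(bundle$coding_calls, file.path(dir, "coding_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$tf_peaks)) {
    write_bed(bundle$tf_peaks, file.path(dir, "tf_peaks.bed"))
  }
  invisible(dir)
}
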