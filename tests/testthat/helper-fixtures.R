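# Shared fixtures, built once per test run.

default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_bundle(sim_config())
    cache
  }
})

# Synthetic genome sequence + annotation for splice-motif tests: coding
# genes carry consensus donor/acceptor motifs; lncRNA genes of each "age"
# group carry the consensus donor with a planted group-specific rate.
splice_fixture <- function(n_coding = 25L, group_rates = c(old = 0.9,
                                                          young = 0.3),
                           n_per_group = 40L, seed = 42L) {
  set.seed(seed)
  donor_cons <- "CAGGTAAGT"      # 3 exonic + 6 intronic
  accep_cons <- "TTTTTTTTTTCAGGG"  # 12 intronic + 3 exonic
  len <- 400000L
  seqchars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  pos <- 1000L
  rows <- list()
  put <- function(s, at) {
    b <- strsplit(s, "")[[1]]
    seqchars[at:(at + length(b) - 1L)] <<- b
  }
  add_gene <- function(id, biotype, strong_donor) {
    e1w <- 200L; iw <- 300L; e2w <- 200L
    s1 <- pos; e1 <- s1 + e1w - 1L
    s2 <- e1 + iw + 1L; e2 <- s2 + e2w - 1L
    pos <<- e2 + 500L
    # donor window [e1-2, e1+6], acceptor window [s2-13, s2+1]
    if (strong_donor) put(donor_cons, e1 - 2L) else {
      put(paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = ""),
          e1 - 2L)
    }
    put(accep_cons, s2 - 13L)
    rows[[length(rows) + 1L]] <<- data.frame(
      start = c(s1, s2), end = c(e1, e2), transcript_id = paste0(id, ".t1"),
      gene_id = id, gene_biotype = biotype)
  }
  for (i in seq_len(n_coding)) {
    add_gene(sprintf("pc%03d", i), "protein_coding", TRUE)
  }
  planted <- list()
  for (g in names(group_rates)) {
    strong <- runif(n_per_group) < group_rates[[g]]
    planted[[g]] <- strong
    for (i in seq_len(n_per_group)) {
      add_gene(sprintf("%s%03d", g, i), "lncRNA", strong[i])
    }
  }
  df <- do.call(rbind, rows)
  exons <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(df$start, df$end),
                                  strand = "+",
                                  transcript_id = df$transcript_id,
                                  gene_id = df$gene_id,
                                  gene_biotype = df$gene_biotype)
  genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- "chrS"
  list(exons = exons, genome = genome, planted = planted)
}
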