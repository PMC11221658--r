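# End-to-end orchestration on a (synthetic or assembled) bundle, plus the
# bundled-fixture arithmetic checks.

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Chains simulate -> classify-coding -> annotate-age -> features ->
#' enrichment and assembles a summary report. With planted ground truth
#' present, recovery metrics (age-label accuracy, uncertain fraction) are
#' included. The run is a pure function of `(config, public)`: identical
#' inputs give identical reports.
#'
#' @param config A [sim_config()].
#' @param public Named character vector of public synteny labels.
#' @param out_dir Optional directory; when given, the bundle and the main
#'   result tables are written there as text files.
#' @return A report list (see details in the package vignette).
#' @export
run_pipeline <- function(config = sim_config(), public = character(0),
                         out_dir = NULL) {
  bundle <- simulate_bundle(config)

  # coding-potential consensus on the simulated call table
  coding_cls <- classify_coding_calls(bundle$coding_calls)
  truth_bio <- setNames(bundle$genes$Q$biotype, bundle$genes$Q$gene_id)
  called_lnc <- coding_cls$loci$gene_id[coding_cls$loci$class == "lncRNA"]
  consensus_recovery <- mean(
    (coding_cls$loci$class == "lncRNA") ==
      (truth_bio[coding_cls$loci$gene_id] == "lncRNA"))

  # minimal-age classification
  ages <- annotate_ages(bundle, public = public)
  truth_age <- bundle$truth$true_age
  asg <- ages$assignments
  asg$true_age <- truth_age[asg$lncrna_id]
  age_recovery <- mean(asg$label == asg$true_age)
  uncertain_fraction <- mean(asg$label == "uncertain")

  # features
  tpm <- compute_tpm(bundle$expression$counts, bundle$expression$lengths_kb)
  cortical <- cortical_filter(tpm, bundle$expression$metadata,
                              bundle$de_clusters)
  mean_tpm_by_age <- tapply(
    rowMeans(tpm)[asg$lncrna_id], truth_age[asg$lncrna_id], mean)
  lnc_spans <- .gene_span_gr(bundle$genes$Q, "lncRNA")
  te <- te_content(lnc_spans, bundle$tes$Q)
  pc_exons <- bundle$annotations$Q[
    mcols(bundle$annotations$Q)$gene_biotype == "protein_coding"]
  pc_spans <- .gene_span_gr(bundle$genes$Q, "protein_coding")
  mgl <- .metagenes_by_gene(bundle$annotations$Q, biotype = "lncRNA")
  positional <- vapply(names(mgl), function(g) {
    classify_positional_type(mgl[[g]], pc_exons, pc_spans)
  }, character(1))

  # enrichment battery
  age_map <- setNames(truth_age, names(truth_age))
  de_genes <- unique(unlist(lapply(bundle$de_clusters,
                                   function(d) d$gene_id)))
  categories <- ifelse(truth_bio == "protein_coding", "protein_coding",
                       unname(age_map[names(truth_bio)]))
  categories <- setNames(categories, names(truth_bio))
  celltype_enrich <- category_enrichment(de_genes, categories,
                                         names(truth_bio))
  spec <- specificity_counts(bundle$de_clusters)
  proms <- extract_promoters(bundle$annotations$Q,
                             chrom_sizes = bundle$chrom_sizes)
  groups <- split(names(categories), categories)
  tf <- tf_promoter_analysis(proms, groups, bundle$tf_peaks,
                             bundle$chrom_sizes,
                             seed = .substream_seed(config$seed, "shuffle"))

  report <- list(
    config = config,
    n_lncrnas = length(truth_age),
    coding_consensus = list(recovery = consensus_recovery,
                            n_called_lncrna_loci = length(called_lnc)),
    ma = list(assignments = asg, age_recovery = age_recovery,
              uncertain_fraction = uncertain_fraction,
              group_counts = table(asg$label)),
    positional = table(positional),
    expression = list(mean_tpm_by_age = mean_tpm_by_age,
                      n_cortical = length(cortical)),
    te = list(has_te_fraction = mean(te$genes$has_te),
              mean_body_fraction = mean(te$genes$gene_body_te_fraction),
              family_counts = table(te$insertions$family)),
    celltype_enrichment = celltype_enrich,
    specificity = table(spec$bins),
    tf = tf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(bundle, file.path(out_dir, "bundle"))
    write.table(asg, file.path(out_dir, "ma_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(coding_cls$loci, file.path(out_dir, "coding_loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(celltype_enrich, file.path(out_dir, "celltype_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Arithmetic consistency checks on the bundled study-design tables
#'
#' The package ships three small reference tables describing the cortical
#' RNA-seq resource the pipeline is modeled on: the per-window/per-region
#' library design, the cortical gene-category counts, and the partition of
#' cortical lncRNAs into age classes. This check recomputes their totals
#' and verifies them against the bundled totals table.
#'
#' @param dir Directory holding the fixture TSVs (defaults to the
#'   package's `extdata`).
#' @return Invisibly, a list of the computed totals; fails with an
#'   informative error when any total disagrees.
#' @export
validate_fixture_tables <- function(dir = system.file("extdata",
                                                      package = "lncage")) {
  lib <- read.delim(file.path(dir, "cortical_library_design.tsv"),
                    check.names = FALSE)
  cats <- read.delim(file.path(dir, "cortical_gene_categories.tsv"))
  part <- read.delim(file.path(dir, "cortical_lncrna_ma_partition.tsv"))
  totals <- read.delim(file.path(dir, "cortical_totals.tsv"))
  tot <- setNames(totals$total, totals$quantity)
  lib_total <- sum(as.matrix(lib[, -1L]))
  cat_total <- sum(cats$count)
  part_total <- sum(part$count)
  checks <- list(
    libraries = c(computed = lib_total, expected = unname(tot["libraries"])),
    cortical_genes = c(computed = cat_total,
                       expected = unname(tot["cortical_genes"])),
    cortical_lncrnas = c(computed = part_total,
                         expected = unname(tot["cortical_lncrnas"])),
    lncrna_category_row = c(
      computed = cats$count[cats$category == "lncRNA"],
      expected = unname(tot["cortical_lncrnas"])))
  for (nm in names(checks)) {
    if (checks[[nm]]["computed"] != checks[[nm]]["expected"]) {
      stop("fixture arithmetic failed for '", nm, "': computed ",
           checks[[nm]]["computed"], ", expected ", checks[[nm]]["expected"])
    }
  }
  invisible(lapply(checks, function(x) x[["computed"]]))
}
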