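## End-to-end orchestration: QC filter once, then every screen, segregation,
## pathway sharing and gene-set enrichment, with a report bundle and run log.

#' Run the full prioritization pipeline
#'
#' Stage order follows the analysis narrative: exclusion filter, candidate
#' screen, stop-gain screen, compound-het search, multiple-hit report,
#' segregation of shortlisted variants (when a pedigree and genotypes are
#' available), pathway sharing and gene-set enrichment (when gene sets are
#' available). All stage outputs are returned and, when `out_dir` is given,
#' written as the TSV report bundle together with a plain-text run log
#' recording the effective configuration, seed and per-stage record counts.
#'
#' @param variants Variant table, or path to a dialect TSV.
#' @param ped Optional `sli_ped` table or PED file path.
#' @param genotypes Optional long genotype table or TSV path (`key`, `iid`,
#'   `gt`).
#' @param gene_sets Optional `gene_set_collection` or GMT path.
#' @param candidate_genes Candidate panel (character vector or file path);
#'   default [candidate_genes_default()].
#' @param cfg A [filter_config()].
#' @param protein_info Optional protein annotation for the stop-gain screen.
#' @param n_perm Permutations for the pathway-sharing test (default 1000).
#' @param seed Seed for the permutation test (default 1).
#' @param out_dir Optional report directory.
#' @return List of class `sli_run`: `qc`, `candidate`, `stopgains`,
#'   `comphet`, `multihit`, `segregation`, `pathway_share`, `enrichment`,
#'   `strata`, `config`.
#' @export
run_all <- function(variants, ped = NULL, genotypes = NULL, gene_sets = NULL,
                    candidate_genes = candidate_genes_default(),
                    cfg = filter_config(), protein_info = NULL,
                    n_perm = 1000L, seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.character(variants)) variants <- stage("read", read_variant_table(variants))
  if (is.character(ped)) ped <- stage("read", read_ped(ped))
  if (is.character(genotypes)) {
    genotypes <- stage("read", utils::read.delim(genotypes,
                                                 stringsAsFactors = FALSE))
  }
  if (is.character(gene_sets)) gene_sets <- stage("read", read_gmt(gene_sets))
  if (is.character(candidate_genes) && length(candidate_genes) == 1 &&
      file.exists(candidate_genes)) {
    candidate_genes <- read_gene_list(candidate_genes)
  }

  qc <- stage("qc_filter", qc_filter(variants, cfg))
  v <- qc$retained
  candidate <- stage("candidate_screen",
                     screen_candidates(v, candidate_genes, cfg))
  stopgains <- stage("stopgain_screen",
                     stopgain_screen(v, cfg, protein_info = protein_info))
  comphet <- stage("comphet", comphet_candidates(v, cfg))
  multihit <- stage("multihit",
                    multihit_probands(candidate$shortlist, stopgains, comphet))

  segregation <- NULL
  if (!is.null(ped) && !is.null(genotypes)) {
    shortlist_all <- rbind(
      candidate$shortlist[, .DIALECT_COLUMNS_INTERNAL, drop = FALSE],
      stopgains[, .DIALECT_COLUMNS_INTERNAL, drop = FALSE]
    )
    segregation <- stage("segregation",
                         segregation_report(shortlist_all, ped, genotypes))
    comphet <- stage("phasing", structure(
      lapply(comphet, phase_comphet, ped = ped, genotypes = genotypes),
      class = "comphet_set"
    ))
  }

  pathway_share <- NULL; enrichment <- NULL
  strata <- stage("stratify", stratify_by_frequency(v, cfg))
  if (!is.null(gene_sets)) {
    gsets <- stage("proband_gene_sets", proband_gene_sets(v, cfg))
    universe <- sort(unique(v$gene))
    pathway_share <- stage("pathway_share",
                           permutation_fdr(gsets, gene_sets, universe,
                                           n_perm = n_perm, seed = seed))
    pooled <- sort(unique(unlist(gsets)))
    enrichment <- stage("enrichment",
                        enrich(pooled, universe, gene_sets, filter = FALSE))
  }

  out <- structure(list(
    qc = qc, candidate = candidate, stopgains = stopgains, comphet = comphet,
    multihit = multihit, segregation = segregation,
    pathway_share = pathway_share, enrichment = enrichment, strata = strata,
    config = list(filter = cfg, n_perm = n_perm, seed = seed)
  ), class = "sli_run")

  if (!is.null(out_dir)) {
    write_report_tables(list(
      candidate_summary = out$candidate$summary,
      candidate_shortlist = out$candidate$shortlist,
      stopgains = out$stopgains,
      comphet = out$comphet,
      multihit = out$multihit,
      segregation = out$segregation,
      pathway_share = out$pathway_share,
      enrichment = out$enrichment
    ), out_dir)
    writeLines(run_log(out), file.path(out_dir, "run_log.txt"))
  }
  out
}

## human-readable run log: effective config and per-stage record counts
run_log <- function(run) {
  cfg <- run$config$filter
  c(
    "sliexome run log",
    "configuration:",
    vapply(names(cfg), function(k) sprintf("  %s = %s", k, format(cfg[[k]])),
           character(1)),
    sprintf("  n_perm = %d", run$config$n_perm),
    sprintf("  seed = %d", run$config$seed),
    "stage record counts:",
    sprintf("  qc_retained = %d", nrow(run$qc$retained)),
    sprintf("  qc_excluded_class = %d", run$qc$excluded["class"]),
    sprintf("  qc_excluded_segdup = %d", run$qc$excluded["segdup"]),
    sprintf("  qc_excluded_depth = %d", run$qc$excluded["depth"]),
    sprintf("  candidate_shortlist = %d", nrow(run$candidate$shortlist)),
    sprintf("  stopgains = %d", nrow(run$stopgains)),
    sprintf("  comphet_groups = %d", length(run$comphet)),
    sprintf("  comphet_genes = %d",
            length(unique(vapply(run$comphet, `[[`, "", "gene")))),
    sprintf("  multihit_probands = %d",
            length(unique(run$multihit$proband))),
    if (!is.null(run$segregation))
      sprintf("  segregation_rows = %d", nrow(run$segregation)),
    if (!is.null(run$pathway_share))
      sprintf("  pathways_tested = %d", nrow(run$pathway_share))
  )
}

#' @export
print.sli_run <- function(x, ...) {
  writeLines(run_log(x))
  invisible(x)
}
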