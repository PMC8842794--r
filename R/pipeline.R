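#' Assemble a validated pipeline configuration
#'
#' Collects the input file paths and every stage threshold in one place.
#' Thresholds are range-checked here so a run fails before any stage
#' executes; every tunable the stages use appears in the manifest of
#' [run_pipeline()], with no hidden constants.
#'
#' @param perturbation_matrix,perturbation_groups Perturbation intensity
#'   matrix TSV and its sample/group table.
#' @param cohort_matrix,cohort_groups Tumor/normal count matrix TSV and
#'   its group table.
#' @param clinical Clinical TSV (`sample`, `time`, `event`).
#' @param network Two-column interaction edge-list TSV.
#' @param gene_sets GMT gene-set file.
#' @param tf_targets Regulator-target TSV.
#' @param out_dir Output directory.
#' @param p_max,fc_min Perturbation DEG thresholds (inclusive).
#' @param fdr_max Cohort DEG / enrichment FDR threshold.
#' @param min_overlap Minimum DEG overlap for a set to be tested.
#' @param enrich_mode `"fdr"` or `"raw"` over-representation rule.
#' @param n_perm GSEA permutations.
#' @param n_random Network randomizations.
#' @param scheme Network randomization scheme.
#' @param module_sets Gene-set names whose DEG members form the network
#'   module group; `NULL` uses the top enriched set.
#' @param concordance_mode `"same"` or `"reversal"`.
#' @param survival_p_max Strict Cox screening threshold.
#' @param seed Master integer seed for every stochastic stage.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(perturbation_matrix, perturbation_groups,
                            cohort_matrix, cohort_groups, clinical,
                            network, gene_sets, tf_targets, out_dir,
                            p_max = 0.05, fc_min = 1.5, fdr_max = 0.05,
                            min_overlap = 5, enrich_mode = "fdr",
                            n_perm = 1000, n_random = 1000,
                            scheme = "degree_preserving",
                            module_sets = NULL,
                            concordance_mode = "same",
                            survival_p_max = 0.05, seed = 1) {
  stopifnot(p_max > 0, p_max <= 1, fc_min >= 1, fdr_max > 0, fdr_max <= 1,
            min_overlap >= 0, n_perm >= 1, n_random >= 1,
            survival_p_max > 0, survival_p_max <= 1)
  scheme <- match.arg(scheme, c("degree_preserving", "label_shuffle"))
  enrich_mode <- match.arg(enrich_mode, c("fdr", "raw"))
  concordance_mode <- match.arg(concordance_mode, c("same", "reversal"))
  seed <- check_seed(seed)
  structure(list(
    paths = list(perturbation_matrix = perturbation_matrix,
                 perturbation_groups = perturbation_groups,
                 cohort_matrix = cohort_matrix,
                 cohort_groups = cohort_groups,
                 clinical = clinical, network = network,
                 gene_sets = gene_sets, tf_targets = tf_targets),
    out_dir = out_dir, p_max = p_max, fc_min = fc_min, fdr_max = fdr_max,
    min_overlap = min_overlap, enrich_mode = enrich_mode, n_perm = n_perm,
    n_random = n_random, scheme = scheme, module_sets = module_sets,
    concordance_mode = concordance_mode, survival_p_max = survival_p_max,
    seed = seed), class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline from input files to a report directory
#'
#' Stage order: perturbation differential expression -> over-representation
#' and preranked GSEA -> network module significance test -> cohort count
#' differential expression -> cross-cohort concordance -> univariate Cox
#' survival screen and contingency -> regulator ranking and candidate
#' nomination. Every stage writes a fixed-name TSV under `out_dir`; a
#' `manifest.json` records the full configuration, seed, and stage output
#' files. Identical configuration and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every in-memory stage result plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  out <- function(f) file.path(config$out_dir, f)
  outputs <- character(0)

  pert <- run_stage("read_inputs", config$out_dir, {
    read_expression_matrix(config$paths$perturbation_matrix,
                           config$paths$perturbation_groups, "intensity")
  })
  sets <- run_stage("read_inputs", config$out_dir,
                    read_gmt(config$paths$gene_sets))
  net <- run_stage("read_inputs", config$out_dir,
                   read_edge_list(config$paths$network))
  tf <- run_stage("read_inputs", config$out_dir,
                  read_tf_targets(config$paths$tf_targets))

  drug_degs <- run_stage("perturbation_deg", config$out_dir, {
    groups <- unique(pert$groups)
    tb <- ttest_fold_change(pert, groups[1], groups[2])
    tb$fdr <- bh_fdr(tb$p)
    call_degs(tb, p_max = config$p_max, fc_min = config$fc_min)
  })
  outputs <- c(outputs, write_tsv(drug_degs, out("deg_perturbation.tsv")))

  ora <- run_stage("enrichment", config$out_dir, {
    enrich(drug_degs, sets, min_overlap = config$min_overlap,
           mode = config$enrich_mode, fdr_max = config$fdr_max)
  })
  outputs <- c(outputs, write_tsv(ora, out("enrichment.tsv")))

  gsea <- run_stage("gsea", config$out_dir, {
    ranked <- stats::setNames(drug_degs$log2fc, drug_degs$gene)
    gsea_preranked(ranked[!drug_degs$degenerate], sets,
                   n_perm = config$n_perm, seed = config$seed + 1L)
  })
  outputs <- c(outputs, write_tsv(gsea, out("gsea.tsv")))

  nettest <- run_stage("network_test", config$out_dir, {
    module_sets <- config$module_sets
    if (is.null(module_sets)) {
      if (!nrow(ora)) stop("no enriched set available to define the module group")
      module_sets <- ora$set[1]
    }
    module_genes <- unique(unlist(sets$sets[module_sets]))
    deg_genes <- drug_degs$gene[drug_degs$is_deg]
    cc_degs <- intersect(deg_genes, module_genes)
    run_network_test(net, cc_degs, setdiff(deg_genes, cc_degs),
                     n_random = config$n_random, scheme = config$scheme,
                     seed = config$seed + 2L)
  })
  outputs <- c(outputs, write_tsv(
    data.frame(statistic = c("ppi_count", "lcc"),
               observed = c(nettest$observed_ppi_count, nettest$observed_lcc),
               empirical_p = c(nettest$empirical_p_ppi,
                               nettest$empirical_p_lcc),
               n_random = nettest$n_random, scheme = nettest$scheme),
    out("network_test.tsv")))
  outputs <- c(outputs, write_tsv(
    data.frame(replicate = seq_len(nettest$n_random),
               null_ppi_count = nettest$null_ppi_counts,
               null_lcc = nettest$null_lccs),
    out("network_null.tsv")))

  coh <- run_stage("cohort_deg", config$out_dir, {
    read_expression_matrix(config$paths$cohort_matrix,
                           config$paths$cohort_groups, "counts")
  })
  tumor_degs <- run_stage("cohort_deg", config$out_dir, {
    groups <- unique(coh$groups)
    ga <- if ("normal" %in% groups) "normal" else groups[1]
    gb <- setdiff(groups, ga)[1]
    count_degs(coh, ga, gb, fdr_max = config$fdr_max)
  })
  outputs <- c(outputs, write_tsv(tumor_degs, out("deg_cohort.tsv")))

  concordance <- run_stage("concordance", config$out_dir, {
    intersect_concordant(drug_degs, tumor_degs,
                         mode = config$concordance_mode)
  })
  outputs <- c(outputs, write_tsv(
    data.frame(gene = concordance$common,
               common_down = concordance$common %in% concordance$common_down,
               common_up = concordance$common %in% concordance$common_up,
               concordant = concordance$common %in% concordance$concordant),
    out("concordance.tsv")))

  cohort <- run_stage("survival", config$out_dir, {
    read_clinical(config$paths$clinical, log2(coh$values + 0.5))
  })
  cox <- run_stage("survival", config$out_dir, {
    screen_genes <- intersect(drug_degs$gene[drug_degs$is_deg],
                              rownames(cohort$expr))
    suppressMessages(cox_screen(cohort, screen_genes))
  })
  outputs <- c(outputs, write_tsv(cox, out("survival_cox.tsv")))
  survival_related <- classify_survival_related(cox,
                                                p_max = config$survival_p_max)

  contingency <- run_stage("contingency", config$out_dir, {
    survival_contingency(cox$gene, survival_related,
                         intersect(drug_degs$gene[drug_degs$is_deg],
                                   cox$gene))
  })
  outputs <- c(outputs, write_tsv(
    data.frame(cell = c("related_altered", "related_unaltered",
                        "unrelated_altered", "unrelated_unaltered"),
               count = as.vector(t(contingency$table)),
               odds_ratio = contingency$odds_ratio, p = contingency$p),
    out("contingency.tsv")))

  regulators <- run_stage("regulators", config$out_dir, {
    rank_regulators(tf, drug_degs$gene[drug_degs$is_deg])
  })
  outputs <- c(outputs, write_tsv(regulators, out("regulators.tsv")))

  candidates <- run_stage("regulators", config$out_dir, {
    suppressMessages(
      nominate_candidates(regulators, cox, tumor_degs, drug_degs,
                          p_max = config$survival_p_max))
  })
  outputs <- c(outputs, write_tsv(candidates, out("candidates.tsv")))

  manifest <- list(config = unclass(config),
                   outputs = basename(outputs),
                   n_stages = 7L)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(drug_degs = drug_degs, enrichment = ora, gsea = gsea,
                 network_test = nettest, tumor_degs = tumor_degs,
                 concordance = concordance, cox = cox,
                 survival_related = survival_related,
                 contingency = contingency, regulators = regulators,
                 candidates = candidates, manifest = manifest))
}
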