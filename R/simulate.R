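# Seed the RNG for the calling function's scope and restore the caller's
# random state (or its absence) on exit, so generators never perturb
# global randomness.
local_rng <- function(seed, envir = parent.frame()) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  withr::defer({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, envir = envir)
  set.seed(seed)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

simulation_truth <- function(genes, module_nodes = character(0),
                             enriched_sets = logical(0)) {
  structure(list(genes = genes, module_nodes = module_nodes,
                 enriched_sets = enriched_sets),
            class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf("SimulationTruth: %d genes (%d DE), %d module nodes, %d sets flagged enriched\n",
              nrow(x$genes), sum(x$genes$is_de), length(x$module_nodes),
              sum(x$enriched_sets)))
  invisible(x)
}

gene_names <- function(n, prefix = "G") {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' Simulate a two-group treated/control intensity experiment
#'
#' Emulates a small drug-perturbation microarray design: log2 intensities
#' are a per-gene baseline plus, for planted differentially expressed (DE)
#' genes, a group shift of magnitude `lfc_location` applied to the treated
#' group, plus Gaussian noise. The sign split of planted effects defaults
#' to 76% down-regulated / 24% up-regulated, the ratio typical of a
#' growth-inhibitory perturbation.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (at least 2; a two-sample t-test
#'   needs replication).
#' @param de_fraction Fraction of genes with a planted effect, in [0, 1].
#' @param lfc_location Magnitude of the planted log2 fold-change.
#' @param sigma Gaussian noise standard deviation (log2 scale).
#' @param down_fraction Fraction of planted effects that are negative.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and seed and does not touch global random state.
#' @return List with elements `expr` (an intensity [expression_matrix()],
#'   groups `ctrl`/`trt`) and `truth` (a `SimulationTruth`).
#' @export
simulate_perturbation <- function(n_genes = 10000, n_per_group = 3,
                                  de_fraction = 0.065, lfc_location = 2,
                                  sigma = 0.5, down_fraction = 0.76,
                                  seed = 1) {
  seed <- check_seed(seed)
  if (n_per_group < 2) {
    stop("`n_per_group` must be at least 2", call. = FALSE)
  }
  if (de_fraction < 0 || de_fraction > 1) {
    stop("`de_fraction` must be in [0, 1]", call. = FALSE)
  }
  local_rng(seed)
  genes <- gene_names(n_genes)
  n_de <- round(de_fraction * n_genes)
  is_de <- rep(FALSE, n_genes)
  is_de[sample.int(n_genes, n_de)] <- TRUE
  lfc <- numeric(n_genes)
  sign_down <- stats::rbinom(n_de, 1, down_fraction) == 1
  lfc[is_de] <- ifelse(sign_down, -lfc_location, lfc_location)
  baseline <- stats::runif(n_genes, 6, 12)
  n <- 2 * n_per_group
  samples <- c(sprintf("ctrl_%d", seq_len(n_per_group)),
               sprintf("trt_%d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("ctrl", "trt"), each = n_per_group), samples)
  mu <- outer(baseline, rep(1, n)) +
    outer(lfc, c(rep(0, n_per_group), rep(1, n_per_group)))
  values <- mu + matrix(stats::rnorm(n_genes * n, sd = sigma), n_genes, n)
  dimnames(values) <- list(genes, samples)
  list(expr = expression_matrix(values, groups, flavor = "intensity"),
       truth = simulation_truth(
         data.frame(gene = genes, is_de = is_de, lfc = lfc, beta = 0,
                    stringsAsFactors = FALSE)))
}

#' Simulate a tumor/normal sequencing count cohort
#'
#' Emulates a case-control RNA-seq cohort: negative-binomial counts with
#' gene-specific log-normal baseline means, a common dispersion, and a
#' `2^lfc` mean multiplier in the tumor group for planted DE genes.
#' Default group sizes mirror a large public tumor cohort with a small
#' adjacent-normal arm.
#'
#' @param n_tumor,n_normal Group sizes (each at least 2).
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes with a planted effect.
#' @param lfc_location Magnitude of the planted log2 fold-change (tumor
#'   relative to normal).
#' @param up_fraction Fraction of planted effects up-regulated in tumor.
#' @param dispersion Common negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param seed Integer seed.
#' @return List with `expr` (a counts [expression_matrix()], groups
#'   `normal`/`tumor`) and `truth`.
#' @export
simulate_cohort <- function(n_tumor = 526, n_normal = 59, n_genes = 10000,
                            de_fraction = 0.6, lfc_location = 1,
                            up_fraction = 0.64, dispersion = 0.4, seed = 1) {
  seed <- check_seed(seed)
  if (n_tumor < 2 || n_normal < 2) {
    stop("both group sizes must be at least 2", call. = FALSE)
  }
  if (dispersion <= 0) stop("`dispersion` must be positive", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("`de_fraction` must be in [0, 1]", call. = FALSE)
  }
  local_rng(seed)
  genes <- gene_names(n_genes)
  n_de <- round(de_fraction * n_genes)
  is_de <- rep(FALSE, n_genes)
  is_de[sample.int(n_genes, n_de)] <- TRUE
  lfc <- numeric(n_genes)
  up <- stats::rbinom(n_de, 1, up_fraction) == 1
  lfc[is_de] <- ifelse(up, lfc_location, -lfc_location)
  base_mu <- exp(stats::rnorm(n_genes, mean = log(200), sd = 1.2))
  n <- n_normal + n_tumor
  samples <- c(sprintf("normal_%03d", seq_len(n_normal)),
               sprintf("tumor_%03d", seq_len(n_tumor)))
  groups <- stats::setNames(rep(c("normal", "tumor"),
                                c(n_normal, n_tumor)), samples)
  mu <- outer(base_mu, rep(1, n)) *
    2^outer(lfc, c(rep(0, n_normal), rep(1, n_tumor)))
  values <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / dispersion),
                   n_genes, n, dimnames = list(genes, samples))
  list(expr = expression_matrix(values, groups, flavor = "counts"),
       truth = simulation_truth(
         data.frame(gene = genes, is_de = is_de, lfc = lfc, beta = 0,
                    stringsAsFactors = FALSE)))
}

#' Simulate survival outcomes linked to expression
#'
#' Event times are exponential with per-sample rate
#' `base_hazard * exp(sum(beta * z))`, where `z` is the standardized
#' (mean 0, unit variance) expression of each risk gene — a
#' proportional-hazards-true generating model. Times beyond `censor_time`
#' are administratively censored.
#'
#' @param expr An `ExpressionMatrix` (or gene-by-sample matrix) providing
#'   covariates.
#' @param risk_genes Named numeric vector: gene -> log hazard ratio beta
#'   per standard deviation of expression. Genes must be rows of `expr`.
#' @param base_hazard Baseline exponential rate (> 0).
#' @param censor_time Administrative censoring time; `Inf` disables
#'   censoring.
#' @param seed Integer seed.
#' @return A [survival_cohort()] over the samples of `expr`.
#' @export
simulate_survival <- function(expr, risk_genes = numeric(0),
                              base_hazard = 0.1, censor_time = Inf,
                              seed = 1) {
  seed <- check_seed(seed)
  if (base_hazard <= 0) stop("`base_hazard` must be positive", call. = FALSE)
  m <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (length(risk_genes)) {
    missing <- setdiff(names(risk_genes), rownames(m))
    if (length(missing)) {
      stop("risk gene(s) not in expression matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  local_rng(seed)
  lp <- rep(0, ncol(m))
  for (g in names(risk_genes)) {
    x <- m[g, ]
    s <- stats::sd(x)
    z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
    lp <- lp + risk_genes[[g]] * z
  }
  t_raw <- stats::rexp(ncol(m), rate = base_hazard * exp(lp))
  event <- as.integer(t_raw <= censor_time)
  time <- pmax(pmin(t_raw, censor_time), 1e-12)
  survival_cohort(stats::setNames(time, colnames(m)),
                  stats::setNames(event, colnames(m)), m)
}

#' Simulate a scale-free interaction network with a planted module
#'
#' Background topology is a Barabasi-Albert preferential-attachment graph
#' (the standard heavy-tailed degree model for protein-protein interaction
#' networks). A chosen subset of nodes is additionally wired among itself
#' until the induced subgraph reaches `planted_density`, planting a
#' dense module whose connectivity the network test should flag.
#'
#' @param n_nodes Number of nodes.
#' @param edges_per_node Edges attached per node during preferential
#'   attachment.
#' @param planted_module_size Number of module nodes (0 disables planting).
#' @param planted_density Target edge density of the induced module
#'   subgraph, in [0, 1].
#' @param seed Integer seed.
#' @return List with `net` (undirected simple `igraph`) and `truth`
#'   (module node names in `truth$module_nodes`).
#' @export
simulate_network <- function(n_nodes = 2000, edges_per_node = 3,
                             planted_module_size = 40,
                             planted_density = 0.5, seed = 1) {
  seed <- check_seed(seed)
  if (planted_module_size > n_nodes) {
    stop("`planted_module_size` cannot exceed `n_nodes`", call. = FALSE)
  }
  if (planted_density < 0 || planted_density > 1) {
    stop("`planted_density` must be in [0, 1]", call. = FALSE)
  }
  local_rng(seed)
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  igraph::V(g)$name <- gene_names(n_nodes)
  g <- igraph::simplify(g)
  module <- character(0)
  if (planted_module_size > 0) {
    module <- sort(sample(igraph::V(g)$name, planted_module_size))
    bg_density <- igraph::edge_density(g)
    if (planted_density < bg_density) {
      warning(sprintf(
        "planted_density (%.4f) is below background density (%.4f); module will not stand out",
        planted_density, bg_density), call. = FALSE)
    }
    n_pairs <- choose(planted_module_size, 2)
    target_edges <- ceiling(planted_density * n_pairs)
    sub <- igraph::induced_subgraph(g, module)
    have <- igraph::ecount(sub)
    if (target_edges > have) {
      pairs <- t(utils::combn(module, 2))
      key <- paste(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
      em <- igraph::as_edgelist(sub)
      have_key <- if (nrow(em)) paste(pmin(em[, 1], em[, 2]),
                                      pmax(em[, 1], em[, 2])) else character(0)
      free <- pairs[!(key %in% have_key), , drop = FALSE]
      add <- free[sample.int(nrow(free), target_edges - have), , drop = FALSE]
      g <- igraph::add_edges(g, as.vector(t(add)))
    }
  }
  list(net = igraph::simplify(g),
       truth = simulation_truth(
         data.frame(gene = gene_names(n_nodes), is_de = FALSE, lfc = 0,
                    beta = 0, stringsAsFactors = FALSE),
         module_nodes = module))
}

#' Simulate gene-set collections with controllable enrichment
#'
#' Background sets draw members uniformly from the gene universe; each
#' requested enriched set draws a stated fraction of its members from the
#' supplied differentially expressed (DE) genes and the rest uniformly
#' from the remaining universe.
#'
#' @param genes Gene universe (character vector).
#' @param de_genes Planted DE genes enriched sets draw from.
#' @param n_sets Number of background sets.
#' @param set_size_range Length-2 integer range of set sizes (uniform).
#' @param enriched_sets Named numeric vector: set name -> fraction of
#'   members drawn from `de_genes`.
#' @param seed Integer seed.
#' @return List with `sets` (a [gene_set_collection()]) and `truth`
#'   (`truth$enriched_sets`, a named logical over all generated sets).
#' @export
simulate_gene_sets <- function(genes, de_genes = character(0), n_sets = 20,
                               set_size_range = c(10, 100),
                               enriched_sets = NULL, seed = 1) {
  seed <- check_seed(seed)
  if (max(set_size_range) > length(genes)) {
    stop("requested set size exceeds gene universe", call. = FALSE)
  }
  if (min(set_size_range) < 5) {
    stop("set sizes below 5 cannot satisfy the downstream minimum-overlap rule",
         call. = FALSE)
  }
  local_rng(seed)
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- stats::setNames(
    lapply(sizes, function(s) sample(genes, s)),
    sprintf("SET_%03d", seq_len(n_sets)))
  enriched_flag <- stats::setNames(rep(FALSE, n_sets), names(sets))
  for (nm in names(enriched_sets)) {
    s <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    n_from_de <- min(round(enriched_sets[[nm]] * s), length(de_genes))
    members <- c(sample(de_genes, n_from_de),
                 sample(setdiff(genes, de_genes), s - n_from_de))
    sets[[nm]] <- members
    enriched_flag[nm] <- TRUE
  }
  list(sets = gene_set_collection(sets),
       truth = simulation_truth(
         data.frame(gene = genes, is_de = genes %in% de_genes, lfc = 0,
                    beta = 0, stringsAsFactors = FALSE),
         enriched_sets = enriched_flag))
}

#' Write a complete synthetic study to disk
#'
#' Generates every input class the pipeline consumes — perturbation
#' intensity matrix, tumor/normal count cohort, clinical table, interaction
#' network, gene sets, and a regulator-target table — plus a ground-truth
#' TSV, all derived from one master seed.
#'
#' @param dir Output directory (created if absent).
#' @param n_genes Number of genes shared by all generated inputs.
#' @param seed Master integer seed; per-file sub-seeds are derived from it.
#' @param ... Passed on to [simulate_perturbation()] and
#'   [simulate_cohort()] (e.g. `de_fraction`).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_inputs <- function(dir, n_genes = 2000, seed = 1, ...) {
  seed <- check_seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pert <- simulate_perturbation(n_genes = n_genes, seed = seed, ...)
  coh <- simulate_cohort(n_genes = n_genes, n_tumor = 120, n_normal = 40,
                         seed = seed + 1L, ...)
  genes <- rownames(pert$expr$values)
  de_genes <- pert$truth$genes$gene[pert$truth$genes$is_de]
  nets <- simulate_network(n_nodes = n_genes, planted_module_size = 40,
                           planted_density = 0.5, seed = seed + 2L)
  gs <- simulate_gene_sets(genes, de_genes, n_sets = 20,
                           set_size_range = c(10, 60),
                           enriched_sets = c(PLANTED_PATHWAY = 0.8),
                           seed = seed + 3L)
  risk <- stats::setNames(c(1, 1), de_genes[1:2])
  cohort <- simulate_survival(coh$expr, risk_genes = risk,
                              base_hazard = 0.1, censor_time = 30,
                              seed = seed + 4L)
  tf <- withr::with_seed(seed + 5L, tf_target_map(
    list(TF_A = de_genes[seq_len(min(30, length(de_genes)))],
         TF_B = sample(genes, 30)),
    class = c("TF", "cofactor")))
  paths <- list(
    perturbation_matrix = file.path(dir, "perturbation_matrix.tsv"),
    perturbation_groups = file.path(dir, "perturbation_groups.tsv"),
    cohort_matrix = file.path(dir, "cohort_matrix.tsv"),
    cohort_groups = file.path(dir, "cohort_groups.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    network = file.path(dir, "network.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    tf_targets = file.path(dir, "tf_targets.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_matrix(pert$expr, paths$perturbation_matrix,
                          paths$perturbation_groups)
  write_expression_matrix(coh$expr, paths$cohort_matrix, paths$cohort_groups)
  write_clinical(cohort, paths$clinical)
  write_edge_list(nets$net, paths$network)
  write_gmt(gs$sets, paths$gene_sets)
  write_tf_targets(tf, paths$tf_targets)
  truth <- pert$truth$genes
  truth$cohort_is_de <- coh$truth$genes$is_de
  truth$cohort_lfc <- coh$truth$genes$lfc
  truth$in_planted_module <- truth$gene %in% nets$truth$module_nodes
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
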