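#' Count interactions between two disjoint gene groups
#'
#' Number of network edges with one endpoint in each group. Genes absent
#' from the network contribute nothing; the groups must be disjoint.
#'
#' @param net An undirected simple `igraph` network.
#' @param group_a,group_b Character vectors of gene symbols.
#' @return Integer edge count.
#' @export
cross_ppi_count <- function(net, group_a, group_b) {
  shared <- intersect(group_a, group_b)
  if (length(shared)) {
    stop("groups overlap: ", paste(utils::head(shared, 10), collapse = ", "),
         call. = FALSE)
  }
  if (!igraph::ecount(net)) return(0L)
  em <- igraph::as_edgelist(net, names = TRUE)
  a1 <- em[, 1] %in% group_a
  a2 <- em[, 2] %in% group_a
  b1 <- em[, 1] %in% group_b
  b2 <- em[, 2] %in% group_b
  sum((a1 & b2) | (a2 & b1))
}

#' Size of the largest connected component induced by a gene group
#'
#' Order of the largest connected component of the subgraph induced by the
#' genes of `group` that are present in the network; 0 when none are.
#'
#' @param net An `igraph` network.
#' @param group Character vector of gene symbols.
#' @return Integer component size.
#' @export
lcc_size <- function(net, group) {
  present <- intersect(group, igraph::V(net)$name)
  if (!length(present)) return(0L)
  sub <- igraph::induced_subgraph(net, present)
  as.integer(max(igraph::components(sub)$csize))
}

#' Randomize a network under a chosen null model
#'
#' `degree_preserving` performs Maslov-Sneppen double-edge swaps
#' (`n_swaps_factor` times the edge count attempted; swaps creating loops
#' or parallel edges are rejected), preserving every node's degree
#' exactly. `label_shuffle` permutes the node identities uniformly,
#' preserving topology but detaching it from gene labels.
#'
#' @param net An undirected simple `igraph` network.
#' @param scheme `"degree_preserving"` or `"label_shuffle"`.
#' @param n_swaps_factor Attempted swaps per edge (degree-preserving).
#' @param seed Integer seed.
#' @return A randomized `igraph` network over the same node names.
#' @export
randomize_network <- function(net,
                              scheme = c("degree_preserving", "label_shuffle"),
                              n_swaps_factor = 10, seed = 1) {
  scheme <- match.arg(scheme)
  seed <- check_seed(seed)
  local_rng(seed)
  randomize_network_impl(net, scheme, n_swaps_factor)
}

# RNG-stream variant used inside the permutation loop: draws from the
# current R random state instead of reseeding per replicate.
randomize_network_impl <- function(net, scheme, n_swaps_factor = 10) {
  if (scheme == "degree_preserving") {
    if (igraph::ecount(net) < 2) {
      stop("degree-preserving randomization needs at least 2 edges",
           call. = FALSE)
    }
    igraph::rewire(net, igraph::keeping_degseq(
      loops = FALSE, niter = n_swaps_factor * igraph::ecount(net)))
  } else {
    perm <- sample(igraph::V(net)$name)
    igraph::set_vertex_attr(net, "name", value = perm)
  }
}

#' Add-one empirical p-value against a null sample
#'
#' `(1 + #exceedances) / (1 + n_null)`: never zero, with floor
#' `1/(n_null + 1)`, so 1,000 randomizations can report at most
#' `p < 10^-3`. Exceedance is non-strict (`>=` for the upper tail).
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics.
#' @param tail `"upper"` or `"lower"`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed, null_values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (!length(null_values)) stop("empty null sample", call. = FALSE)
  exceed <- if (tail == "upper") sum(null_values >= observed)
            else sum(null_values <= observed)
  (1 + exceed) / (1 + length(null_values))
}

#' Network-module significance test against randomized networks
#'
#' Computes two observed statistics — the number of interactions between a
#' module gene group and a second gene group, and the largest connected
#' component (LCC) of the module's induced subgraph — then recomputes both
#' on `n_random` randomized networks with the node groups held fixed (the
#' network, not the group membership, is the random object). Empirical
#' p-values use the add-one rule, so the smallest attainable p at 1,000
#' randomizations is `1/1001`.
#'
#' @param net An undirected simple `igraph` network.
#' @param cc_degs Module gene group (e.g. cell-cycle DEGs).
#' @param other_degs Second gene group, disjoint from `cc_degs` (e.g. all
#'   remaining DEGs).
#' @param n_random Number of randomized networks.
#' @param scheme Randomization scheme, see [randomize_network()].
#' @param n_swaps_factor Attempted swaps per edge (degree-preserving).
#' @param seed Integer seed.
#' @return Object of class `NetworkTestResult`: observed statistics, full
#'   null distributions, both empirical p-values, and the scheme/seed
#'   bookkeeping.
#' @export
run_network_test <- function(net, cc_degs, other_degs, n_random = 1000,
                             scheme = c("degree_preserving", "label_shuffle"),
                             n_swaps_factor = 10, seed = 1) {
  scheme <- match.arg(scheme)
  seed <- check_seed(seed)
  observed_ppi <- cross_ppi_count(net, cc_degs, other_degs)
  observed_lcc <- lcc_size(net, cc_degs)
  null_ppi <- numeric(n_random)
  null_lcc <- numeric(n_random)
  local_rng(seed)
  for (i in seq_len(n_random)) {
    r <- randomize_network_impl(net, scheme, n_swaps_factor)
    null_ppi[i] <- cross_ppi_count(r, cc_degs, other_degs)
    null_lcc[i] <- lcc_size(r, cc_degs)
  }
  structure(list(observed_ppi_count = observed_ppi,
                 observed_lcc = observed_lcc,
                 null_ppi_counts = null_ppi,
                 null_lccs = null_lcc,
                 empirical_p_ppi = empirical_p(observed_ppi, null_ppi),
                 empirical_p_lcc = empirical_p(observed_lcc, null_lcc),
                 n_random = n_random,
                 scheme = scheme,
                 seed = seed),
            class = "NetworkTestResult")
}

#' @export
print.NetworkTestResult <- function(x, ...) {
  cat(sprintf(paste0(
    "Network module significance test (%s, %d randomizations, seed %d)\n",
    "  cross-group interactions: observed %d, null mean %.1f, empirical p = %.4g\n",
    "  largest connected component: observed %d, null mean %.1f, empirical p = %.4g\n"),
    x$scheme, x$n_random, x$seed,
    x$observed_ppi_count, mean(x$null_ppi_counts), x$empirical_p_ppi,
    x$observed_lcc, mean(x$null_lccs), x$empirical_p_lcc))
  invisible(x)
}
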