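#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` members of a `K`-gene set when `n`
#' genes are drawn without replacement from a universe of `N`.
#'
#' @param N Universe size.
#' @param K Gene-set size within the universe.
#' @param n Query (e.g. DEG list) size.
#' @param k Observed overlap.
#' @return The upper-tail p-value.
#' @export
hypergeom_overrep <- function(N, K, n, k) {
  if (K > N || n > N || k < 0 || k > min(K, n)) {
    stop("invalid hypergeometric parameters: need K <= N, n <= N, 0 <= k <= min(K, n)",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis of a DEG list
#'
#' One hypergeometric upper-tail test per gene set against the measured
#' universe; sets overlapping the DEG list by fewer than `min_overlap`
#' genes are excluded before testing. Two significance modes mirror common
#' practice for different collections: `"fdr"` flags sets with BH-adjusted
#' p below `fdr_max`, `"raw"` flags sets with unadjusted p below `p_max`
#' (both strict).
#'
#' @param degs A DEG table (rows with `is_deg` are used) or a character
#'   vector of DEG symbols.
#' @param sets A [gene_set_collection()].
#' @param universe Character vector of all measured genes; defaults to the
#'   genes of the DEG table. Must contain every DEG.
#' @param min_overlap Minimum DEG overlap for a set to be tested.
#' @param mode `"fdr"` or `"raw"` significance rule.
#' @param fdr_max,p_max Thresholds for the two modes (strict `<`).
#' @return `data.frame` with columns `set`, `N`, `K`, `n`, `k`, `p`,
#'   `fdr`, `significant`, `overlap_genes` (semicolon-separated), ordered
#'   by p.
#' @export
enrich <- function(degs, sets, universe = NULL, min_overlap = 5,
                   mode = c("fdr", "raw"), fdr_max = 0.05, p_max = 0.05) {
  mode <- match.arg(mode)
  if (is.data.frame(degs)) {
    if (is.null(universe)) universe <- degs$gene
    degs <- degs$gene[degs$is_deg]
  }
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  missing <- setdiff(degs, universe)
  if (length(missing)) {
    stop("DEG(s) outside the universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  degs <- unique(degs)
  N <- length(universe)
  n <- length(degs)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    ov <- intersect(members, degs)
    if (length(ov) < min_overlap) return(NULL)
    data.frame(set = nm, N = N, K = length(members), n = n,
               k = length(ov),
               p = hypergeom_overrep(N, length(members), n, length(ov)),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      overlap_genes = character(0))
  }
  out$fdr <- bh_fdr(out$p)
  out$significant <- if (mode == "fdr") out$fdr < fdr_max else out$p < p_max
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "N", "K", "n", "k", "p", "fdr", "significant",
          "overlap_genes")]
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score. `w` = |ranking
# score|^weight in ranked order; `hit` = logical membership in ranked order.
# Returns the signed maximum deviation and its position.
gsea_running_es <- function(w, hit) {
  n <- length(hit)
  nh <- sum(hit)
  denom <- sum(w[hit])
  inc <- if (denom > 0) w / denom else rep(1 / nh, n)
  step <- ifelse(hit, inc, -1 / (n - nh))
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak)
}

#' Preranked gene set enrichment analysis
#'
#' Genes are ordered by a per-gene ranking score (typically log2 fold
#' change, largest first). For each set, the enrichment score (ES) is the
#' signed maximum deviation of a weighted Kolmogorov-Smirnov running sum:
#' each in-set gene ("hit") adds its `|score|^weight` divided by the set's
#' total hit weight, each out-of-set gene subtracts `1/(N - |S|)`. The
#' null distribution comes from `n_perm` random gene sets of the same
#' size; the normalized enrichment score (NES) divides ES by the mean
#' absolute null ES of matching sign, and the p-value is the add-one
#' empirical tail proportion among matching-sign null scores. P-values are
#' BH-adjusted across sets.
#'
#' Sets with fewer than 2 members in the ranking, or covering the entire
#' ranking (no misses, so the miss increment is undefined), are skipped
#' with a message.
#'
#' @param ranked Named numeric vector: gene -> ranking score (finite).
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of random-set permutations for the null.
#' @param weight Exponent applied to |score| for hit increments (1 =
#'   classic weighted statistic; 0 = unweighted Kolmogorov-Smirnov).
#' @param seed Integer seed for the permutation null.
#' @return `data.frame` with columns `set`, `size`, `es`, `nes`, `p`,
#'   `p_adjust`, `leading_edge` (semicolon-separated), ordered by p.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight = 1,
                           seed = 1) {
  seed <- check_seed(seed)
  if (anyNA(ranked) || any(!is.finite(ranked))) {
    stop("ranking scores must be finite", call. = FALSE)
  }
  if (is.null(names(ranked)) || anyDuplicated(names(ranked))) {
    stop("`ranked` must be named by unique gene ids", call. = FALSE)
  }
  ord <- order(ranked, decreasing = TRUE)
  genes <- names(ranked)[ord]
  scores <- ranked[ord]
  w <- abs(scores)^weight
  n <- length(genes)
  local_rng(seed)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], genes)
    if (length(members) < 2) {
      message(sprintf("gsea_preranked: skipping '%s' (<2 members in ranking)", nm))
      return(NULL)
    }
    if (length(members) == n) {
      message(sprintf("gsea_preranked: skipping '%s' (covers the whole ranking)", nm))
      return(NULL)
    }
    hit <- genes %in% members
    obs <- gsea_running_es(w, hit)
    nh <- length(members)
    null_es <- vapply(seq_len(n_perm), function(i) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      gsea_running_es(w, h)$es
    }, numeric(1))
    same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
    denom <- mean(abs(same_sign))
    nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
    le <- if (obs$es >= 0) genes[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
          else genes[obs$peak:n][hit[obs$peak:n]]
    data.frame(set = nm, size = nh, es = obs$es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0),
                      leading_edge = character(0))
  }
  out$p_adjust <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "size", "es", "nes", "p", "p_adjust", "leading_edge")]
}
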