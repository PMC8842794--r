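#' Two-sample t-test and fold change per gene on an intensity matrix
#'
#' Classical pooled-variance (Student) two-sample t-test per gene on log2
#' intensities, two-sided. The linear fold change is `2^(mean_b - mean_a)`
#' of the log2 values, so direction is reported relative to the second
#' (treated) group. Genes with zero pooled variance are handled without
#' infinite statistics: equal group means give `t = 0, p = 1`; unequal
#' means with zero variance are flagged `degenerate` (statistic and p set
#' to `NA`) and excluded from downstream DEG calling.
#'
#' @param expr An intensity-flavor [expression_matrix()].
#' @param group_a,group_b Group labels; `group_b` is the treated/test
#'   group.
#' @return A DEG table: `data.frame` with columns `gene`, `statistic`,
#'   `p`, `fdr`, `fc` (linear), `log2fc`, `direction` (`up`/`down`
#'   relative to `group_b`), `degenerate`, `is_deg` (all `FALSE` until
#'   [call_degs()]).
#' @export
ttest_fold_change <- function(expr, group_a, group_b) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$flavor != "intensity") {
    stop("ttest_fold_change requires intensity flavor", call. = FALSE)
  }
  a <- group_samples(expr, group_a)
  b <- group_samples(expr, group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  xa <- expr$values[, a, drop = FALSE]
  xb <- expr$values[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- mb - ma
  stat <- diff / se
  p <- 2 * stats::pt(-abs(stat), df = na + nb - 2)
  zero_var <- se == 0
  degenerate <- zero_var & diff != 0
  stat[zero_var & diff == 0] <- 0
  p[zero_var & diff == 0] <- 1
  stat[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  if (any(degenerate)) {
    message(sprintf("ttest_fold_change: %d gene(s) with zero variance and unequal means flagged degenerate",
                    sum(degenerate)))
  }
  deg_table(gene = rownames(expr$values), statistic = stat, p = p,
            log2fc = diff, degenerate = degenerate)
}

deg_table <- function(gene, statistic, p, log2fc,
                      degenerate = rep(FALSE, length(gene)),
                      fdr = rep(NA_real_, length(gene))) {
  data.frame(gene = gene, statistic = statistic, p = p, fdr = fdr,
             fc = 2^log2fc, log2fc = log2fc,
             direction = ifelse(log2fc > 0, "up", "down"),
             degenerate = degenerate,
             is_deg = rep(FALSE, length(gene)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse a probe-level DEG table to one row per gene
#'
#' Keeps, per gene, the most statistically significant probe (smallest raw
#' p). Ties on p are broken by larger absolute log2 fold-change, then by
#' lexicographically smallest probe id, so the output is deterministic.
#' Probes absent from the mapping are dropped with a message reporting how
#' many.
#'
#' @param table A probe-level DEG table (`gene` column holds probe ids).
#' @param probe_to_gene Named character vector: probe id -> gene symbol.
#' @return A gene-level DEG table with an extra `probe` column recording
#'   the surviving probe.
#' @export
collapse_probes <- function(table, probe_to_gene) {
  if (!nrow(table)) {
    out <- table
    out$probe <- character(0)
    return(out)
  }
  mapped <- table$gene %in% names(probe_to_gene)
  if (any(!mapped)) {
    message(sprintf("collapse_probes: dropped %d unmapped probe(s)",
                    sum(!mapped)))
  }
  tb <- table[mapped, , drop = FALSE]
  if (!nrow(tb)) {
    out <- tb
    out$probe <- character(0)
    return(out)
  }
  tb$probe <- tb$gene
  tb$gene <- unname(probe_to_gene[tb$probe])
  # degenerate probes (p = NA) sort last so a testable probe always wins
  ord <- order(tb$gene, xtfrm(tb$p), -abs(tb$log2fc), tb$probe,
               na.last = TRUE)
  tb <- tb[ord, , drop = FALSE]
  tb <- tb[!duplicated(tb$gene), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

#' Call differentially expressed genes on a DEG table
#'
#' Inclusive thresholds: a gene is a DEG when `p <= p_max` and its linear
#' fold change is at least `fc_min` in either direction (`fc >= fc_min` or
#' `fc <= 1/fc_min`). Degenerate genes are never called.
#'
#' @param table A DEG table.
#' @param p_max Raw p-value threshold (inclusive).
#' @param fc_min Linear fold-change threshold (inclusive, must be >= 1).
#' @return The table with `is_deg` filled in.
#' @export
call_degs <- function(table, p_max = 0.05, fc_min = 1.5) {
  if (fc_min < 1) stop("`fc_min` must be at least 1", call. = FALSE)
  table$is_deg <- !table$degenerate & !is.na(table$p) &
    table$p <= p_max & (table$fc >= fc_min | table$fc <= 1 / fc_min)
  table
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; output is monotone
#' non-decreasing in the rank of the raw p-value and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1] (`NA` allowed,
#'   propagated).
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Count-based differential expression (logCPM + Welch t + BH)
#'
#' Library sizes are normalized to counts-per-million, log2-transformed
#' with a 0.5 pseudocount, and compared between groups with a Welch
#' (unequal-variance) t-test; significance is controlled by
#' Benjamini-Hochberg FDR. Fold change is computed from the group mean
#' logCPM difference, direction relative to `group_b`.
#'
#' @param expr A counts-flavor [expression_matrix()].
#' @param group_a,group_b Group labels (`group_b` = tumor/test group).
#' @param fdr_max FDR threshold (inclusive) for the `is_deg` call.
#' @return A DEG table (see [ttest_fold_change()]) with `is_deg` set by
#'   `fdr <= fdr_max`.
#' @export
count_degs <- function(expr, group_a, group_b, fdr_max = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$flavor != "counts") {
    stop("count_degs requires counts flavor", call. = FALSE)
  }
  a <- group_samples(expr, group_a)
  b <- group_samples(expr, group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (!nrow(expr$values)) {
    return(deg_table(character(0), numeric(0), numeric(0), numeric(0)))
  }
  lib <- colSums(expr$values)
  if (any(lib == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(expr$values)[lib == 0], collapse = ", "),
         call. = FALSE)
  }
  logcpm <- log2(sweep(expr$values, 2, lib, "/") * 1e6 + 0.5)
  xa <- logcpm[, a, drop = FALSE]
  xb <- logcpm[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- mb - ma
  stat <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, NA_real_))
  # Welch-Satterthwaite degrees of freedom
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.na(stat), NA_real_,
              ifelse(stat == 0 & se2 == 0, 1,
                     2 * stats::pt(-abs(stat), df = df)))
  degenerate <- is.na(stat)
  tb <- deg_table(gene = rownames(expr$values), statistic = stat, p = p,
                  log2fc = diff, degenerate = degenerate)
  tb$fdr <- bh_fdr(tb$p)
  tb$is_deg <- !tb$degenerate & !is.na(tb$fdr) & tb$fdr <= fdr_max
  tb
}
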