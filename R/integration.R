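#' Cross-cohort DEG concordance bookkeeping
#'
#' Intersects two DEG tables (e.g. a drug-perturbation screen and a
#' tumor-vs-normal cohort) and classifies the common genes by direction.
#' `common_down`/`common_up` always record genes called in the same
#' direction in both tables. The `concordant` set depends on `mode`:
#' `"same"` keeps same-direction genes (the usual common-DEG bookkeeping),
#' `"reversal"` keeps opposite-direction genes (a drug pushing tumor-up
#' genes down).
#'
#' @param a,b DEG tables carrying `gene`, `direction`, `is_deg`.
#' @param mode `"same"` or `"reversal"`.
#' @return Object of class `ConcordanceResult`: `common`, `common_down`,
#'   `common_up`, `concordant`, `discordant`, `mode`.
#' @export
intersect_concordant <- function(a, b, mode = c("same", "reversal")) {
  mode <- match.arg(mode)
  for (tb in list(a, b)) {
    if (!all(c("gene", "direction", "is_deg") %in% names(tb))) {
      stop("DEG tables must carry 'gene', 'direction', 'is_deg' columns",
           call. = FALSE)
    }
    if (any(tb$is_deg & (is.na(tb$direction) |
                         !tb$direction %in% c("up", "down")))) {
      stop("DEG with missing direction", call. = FALSE)
    }
  }
  da <- a[a$is_deg, ]
  db <- b[b$is_deg, ]
  common <- intersect(da$gene, db$gene)
  dir_a <- stats::setNames(da$direction, da$gene)[common]
  dir_b <- stats::setNames(db$direction, db$gene)[common]
  same <- common[dir_a == dir_b]
  opposite <- setdiff(common, same)
  common_down <- common[dir_a == "down" & dir_b == "down"]
  common_up <- common[dir_a == "up" & dir_b == "up"]
  concordant <- if (mode == "same") same else opposite
  structure(list(common = common,
                 common_down = common_down,
                 common_up = common_up,
                 concordant = concordant,
                 discordant = setdiff(common, concordant),
                 mode = mode),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Concordance (%s mode): %d common DEGs, %d common down, %d common up, %d concordant, %d discordant\n",
              x$mode, length(x$common), length(x$common_down),
              length(x$common_up), length(x$concordant),
              length(x$discordant)))
  invisible(x)
}

#' Survival-related by drug-altered contingency test
#'
#' Builds the 2x2 table of DEGs cross-classified by survival relation and
#' drug alteration, and tests over-representation of drug-altered genes
#' among survival-related ones with a one-sided Fisher exact test.
#'
#' @param all_degs Universe of genes entering the table.
#' @param survival_related,drug_altered Subsets of `all_degs`.
#' @return Object of class `ContingencyResult`: `table` (2x2 matrix),
#'   `odds_ratio` (sample OR), `p` (one-sided Fisher),
#'   `prop_survival_altered` (share of survival-related genes that are
#'   drug-altered).
#' @export
survival_contingency <- function(all_degs, survival_related, drug_altered) {
  all_degs <- unique(all_degs)
  if (!length(all_degs)) stop("empty gene universe", call. = FALSE)
  bad <- c(setdiff(survival_related, all_degs),
           setdiff(drug_altered, all_degs))
  if (length(bad)) {
    stop("genes outside `all_degs`: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  surv <- all_degs %in% survival_related
  drug <- all_degs %in% drug_altered
  tab <- matrix(c(sum(surv & drug), sum(surv & !drug),
                  sum(!surv & drug), sum(!surv & !drug)),
                nrow = 2, byrow = TRUE,
                dimnames = list(survival = c("related", "unrelated"),
                                drug = c("altered", "unaltered")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warning("degenerate contingency margin; no enrichment testable",
            call. = FALSE)
    p <- 1
  } else {
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(table = tab, odds_ratio = or, p = p,
                 prop_survival_altered =
                   if (sum(surv)) sum(surv & drug) / sum(surv) else NA_real_),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat("Survival x drug-altered contingency:\n")
  print(x$table)
  cat(sprintf("  odds ratio %.3f, one-sided Fisher p = %.4g; %.1f%% of survival-related genes drug-altered\n",
              x$odds_ratio, x$p, 100 * x$prop_survival_altered))
  invisible(x)
}

#' Rank regulators by pathway-DEG target count
#'
#' Counts, for each regulator, how many of its annotated targets fall in
#' the supplied pathway DEG set; output is sorted by descending count with
#' lexicographic tie-breaking.
#'
#' @param tf_map A [tf_target_map()].
#' @param pathway_degs Character vector of pathway DEG symbols.
#' @return `data.frame` with columns `regulator`, `class`,
#'   `target_count`.
#' @export
rank_regulators <- function(tf_map, pathway_degs) {
  stopifnot(inherits(tf_map, "TFTargetMap"))
  counts <- vapply(tf_map$targets,
                   function(t) length(intersect(t, pathway_degs)),
                   integer(1))
  out <- data.frame(regulator = names(tf_map$targets),
                    class = unname(tf_map$class),
                    target_count = unname(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$target_count, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate candidate regulators by four evidence criteria
#'
#' A regulator is retained when (i) its univariate Cox Wald p is strictly
#' below `p_max`, (ii) its hazard direction is HR > 1 (high expression,
#' worse survival), (iii) it is an up-regulated DEG in the tumor cohort
#' table, and (iv) it is a down-regulated DEG in the drug perturbation
#' table. A regulator missing from any evidence table cannot be evaluated
#' and is excluded with a message.
#'
#' @param regulators `data.frame` from [rank_regulators()] (or a
#'   character vector of regulator symbols).
#' @param cox Cox result `data.frame` (from [cox_screen()]).
#' @param tumor_degs,drug_degs DEG tables for the cohort and perturbation
#'   screens.
#' @param p_max Strict Cox p-value threshold.
#' @return `data.frame` of retained regulators with the four evidence
#'   columns (`cox_p`, `hr`, `tumor_direction`, `drug_direction`),
#'   input-order stable.
#' @export
nominate_candidates <- function(regulators, cox, tumor_degs, drug_degs,
                                p_max = 0.05) {
  regs <- if (is.data.frame(regulators)) regulators$regulator
          else as.character(regulators)
  rows <- lapply(regs, function(r) {
    ic <- match(r, cox$gene)
    it <- match(r, tumor_degs$gene)
    id <- match(r, drug_degs$gene)
    if (is.na(ic) || is.na(it) || is.na(id)) {
      message("nominate_candidates: '", r,
              "' not evaluable (absent from an evidence table); excluded")
      return(NULL)
    }
    keep <- !is.na(cox$p[ic]) && cox$p[ic] < p_max &&
      cox$beta[ic] > 0 &&
      tumor_degs$is_deg[it] && tumor_degs$direction[it] == "up" &&
      drug_degs$is_deg[id] && drug_degs$direction[id] == "down"
    if (!keep) return(NULL)
    data.frame(regulator = r, cox_p = cox$p[ic], hr = cox$hr[ic],
               tumor_direction = tumor_degs$direction[it],
               drug_direction = drug_degs$direction[id],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(regulator = character(0), cox_p = numeric(0),
                      hr = numeric(0), tumor_direction = character(0),
                      drug_direction = character(0))
  }
  out
}
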