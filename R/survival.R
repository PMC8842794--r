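#' Univariate Cox proportional-hazards fit for one gene
#'
#' Fits `Surv(time, event) ~ expression` by partial-likelihood
#' maximization with Efron handling of tied event times. The covariate is
#' entered as continuous expression, by default standardized to unit
#' variance so hazard ratios are per standard deviation. A positive
#' coefficient (HR > 1) means high expression associates with worse
#' survival.
#'
#' @param cohort A [survival_cohort()].
#' @param gene Gene symbol (must be a row of the cohort expression).
#' @param standardize Standardize the covariate to mean 0, unit variance.
#' @return One-row `data.frame`: `gene`, `beta`, `se`, `z`, `p`, `hr`,
#'   `direction` (`"high_worse"` when beta > 0, else `"high_better"`),
#'   `converged`.
#' @export
cox_univariate <- function(cohort, gene, standardize = TRUE) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  if (!gene %in% rownames(cohort$expr)) {
    stop("gene '", gene, "' not in cohort expression", call. = FALSE)
  }
  if (sum(cohort$event) < 1) {
    stop("no events in cohort; Cox model cannot be fit", call. = FALSE)
  }
  x <- cohort$expr[gene, ]
  if (stats::sd(x) == 0) {
    stop("no variation in covariate for gene '", gene, "'", call. = FALSE)
  }
  if (standardize) x <- (x - mean(x)) / stats::sd(x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(cohort$time, cohort$event) ~ x,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  data.frame(gene = gene, beta = beta,
             se = unname(s$coefficients[, "se(coef)"]),
             z = unname(s$coefficients[, "z"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             hr = exp(beta),
             direction = if (beta > 0) "high_worse" else "high_better",
             converged = converged,
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen over many genes
#'
#' Runs [cox_univariate()] per gene; genes whose fit is impossible
#' (constant covariate) are skipped with a message.
#'
#' @param cohort A [survival_cohort()].
#' @param genes Genes to screen (default: all rows of the cohort).
#' @param standardize Passed to [cox_univariate()].
#' @return `data.frame` of per-gene Cox results.
#' @export
cox_screen <- function(cohort, genes = rownames(cohort$expr),
                       standardize = TRUE) {
  rows <- lapply(genes, function(g) {
    tryCatch(cox_univariate(cohort, g, standardize = standardize),
             error = function(e) {
               if (grepl("no events", conditionMessage(e))) stop(e)
               message("cox_screen: skipping ", g, " (",
                       conditionMessage(e), ")")
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), beta = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0),
                      hr = numeric(0), direction = character(0),
                      converged = logical(0))
  }
  out
}

#' Classify survival-related genes from Cox screen results
#'
#' Strict threshold: a gene is survival-related when its Wald p-value is
#' strictly below `p_max`.
#'
#' @param results Cox result `data.frame` (from [cox_screen()]).
#' @param p_max Strict p-value threshold.
#' @return Character vector of survival-related gene symbols.
#' @export
classify_survival_related <- function(results, p_max = 0.05) {
  if (!nrow(results)) return(character(0))
  results$gene[!is.na(results$p) & results$p < p_max]
}

#' Kaplan-Meier comparison of median-split expression groups
#'
#' Samples with expression strictly above the cohort median form the
#' `high` group, the rest the `low` group. Each group gets a
#' product-limit survival estimate and the groups are compared with the
#' two-group log-rank test.
#'
#' @param cohort A [survival_cohort()].
#' @param gene Gene symbol to split on.
#' @return Object of class `KMResult`: `curves` (`data.frame` of
#'   `group`, `time`, `surv`, `n_risk`, `n_event`), `chisq`, `p`
#'   (log-rank), `n_high`, `n_low`.
#' @export
km_median_split <- function(cohort, gene) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  if (!gene %in% rownames(cohort$expr)) {
    stop("gene '", gene, "' not in cohort expression", call. = FALSE)
  }
  x <- cohort$expr[gene, ]
  med <- stats::median(x)
  grp <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) < 2) || length(unique(grp)) < 2) {
    stop("no split: median dichotomization leaves a group with fewer than 2 samples",
         call. = FALSE)
  }
  surv_obj <- survival::Surv(cohort$time, cohort$event)
  fit <- survival::survfit(surv_obj ~ grp)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^grp=", "", strata), time = fit$time,
                       surv = fit$surv, n_risk = fit$n.risk,
                       n_event = fit$n.event, stringsAsFactors = FALSE)
  lr <- survival::survdiff(surv_obj ~ grp)
  p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(lr$chisq), p = p,
                 n_high = sum(grp == "high"), n_low = sum(grp == "low"),
                 gene = gene),
            class = "KMResult")
}

#' @export
print.KMResult <- function(x, ...) {
  cat(sprintf("Kaplan-Meier median split on %s: high n=%d, low n=%d, log-rank chisq=%.3f, p=%.4g\n",
              x$gene, x$n_high, x$n_low, x$chisq, x$p))
  invisible(x)
}
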