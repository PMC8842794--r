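# Small in-code fixtures shared across test files.

make_intensity <- function(values, groups = NULL) {
  if (is.null(groups)) {
    half <- ncol(values) / 2
    groups <- stats::setNames(rep(c("a", "b"), each = half),
                              colnames(values))
  }
  expression_matrix(values, groups, flavor = "intensity")
}

# Two-group intensity matrix from per-group row lists:
# rows = list(gene = list(a = c(...), b = c(...)), ...)
two_group_expr <- function(rows) {
  na <- length(rows[[1]]$a); nb <- length(rows[[1]]$b)
  m <- t(vapply(rows, function(r) c(r$a, r$b), numeric(na + nb)))
  colnames(m) <- c(sprintf("a%d", seq_len(na)), sprintf("b%d", seq_len(nb)))
  rownames(m) <- names(rows)
  make_intensity(m, stats::setNames(rep(c("grpA", "grpB"), c(na, nb)),
                                    colnames(m)))
}

path_graph <- function(...) {
  nodes <- c(...)
  interaction_network(cbind(nodes[-length(nodes)], nodes[-1]))
}

tiny_cohort <- function(time, event, x, gene = "G1") {
  m <- matrix(x, nrow = 1,
              dimnames = list(gene, sprintf("s%d", seq_along(x))))
  survival_cohort(time, event, m)
}

random_cox_cohort <- function(n, beta = 0, seed) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    t_raw <- stats::rexp(n, rate = 0.2 * exp(beta * x))
    cens <- stats::rexp(n, rate = 0.1)
    tiny_cohort(pmin(t_raw, cens), as.integer(t_raw <= cens), x)
  })
}
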