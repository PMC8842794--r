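# Independent brute-force oracles, deliberately written from the
# definitions rather than sharing code with the package implementation.

# Benjamini-Hochberg step-up from the definition: adj_(i) is the minimum
# over j >= i of p_(j) * n / j, capped at 1, mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
# of n balls from an urn with K white balls: returns P(X >= k).
hyper_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Cox partial log-likelihood (no tied event times in oracle cohorts, so
# Breslow and Efron coincide), evaluated on a beta grid.
cox_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_grid_beta <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  # vectorized over the grid: loglik(beta) = sum_i [beta x_i - logsumexp]
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- rep(0, length(grid))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + outer(grid, x[i]) - log(exp(outer(grid, x[risk])) %*%
                                         rep(1, sum(risk)))
  }
  grid[which.max(ll)]
}

# GSEA running-sum enrichment score by explicit position-by-position loop.
es_oracle <- function(ranked, set, weight = 1) {
  ord <- order(ranked, decreasing = TRUE)
  genes <- names(ranked)[ord]
  scores <- ranked[ord]
  n <- length(genes)
  hit <- genes %in% set
  denom <- sum(abs(scores[hit])^weight)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      running <- running + abs(scores[i])^weight / denom
    } else {
      running <- running - 1 / (n - sum(hit))
    }
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}
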