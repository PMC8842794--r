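deg_row <- function(gene, direction, is_deg = TRUE) {
  data.frame(gene = gene, statistic = 1, p = 0.01, fdr = 0.01,
             fc = ifelse(direction == "up", 2, 0.5),
             log2fc = ifelse(direction == "up", 1, -1),
             direction = direction, degenerate = FALSE, is_deg = is_deg,
             stringsAsFactors = FALSE)
}

test_that("cross-cohort concordance bookkeeping follows set algebra", {
  a <- deg_row(c("g1", "g2", "g3"), c("up", "down", "up"))
  b <- deg_row(c("g1", "g2", "g4"), c("up", "up", "down"))
  res <- intersect_concordant(a, b, mode = "same")
  expect_setequal(res$common, c("g1", "g2"))
  expect_equal(res$concordant, "g1")
  expect_equal(res$discordant, "g2")
  expect_equal(res$common_up, "g1")
  expect_length(res$common_down, 0)

  rev_mode <- intersect_concordant(a, b, mode = "reversal")
  expect_equal(rev_mode$concordant, "g2")
  expect_equal(rev_mode$discordant, "g1")

  # disjoint lists: all empty
  empty <- intersect_concordant(a, deg_row("g9", "up"))
  expect_length(empty$common, 0)
  expect_length(empty$concordant, 0)

  # a table against itself in same mode: everything concordant
  self <- intersect_concordant(a, a, mode = "same")
  expect_setequal(self$concordant, c("g1", "g2", "g3"))
  expect_equal(length(self$common_down) + length(self$common_up),
               length(self$concordant))

  bad <- a; bad$direction[1] <- NA
  expect_error(intersect_concordant(bad, b), "direction")
})

test_that("concordant and discordant sets always partition the common set", {
  for (i in 1:20) {
    withr::with_seed(700 + i, {
      genes_a <- sample(paste0("g", 1:30), 15)
      genes_b <- sample(paste0("g", 1:30), 15)
      a <- deg_row(genes_a, sample(c("up", "down"), 15, TRUE))
      b <- deg_row(genes_b, sample(c("up", "down"), 15, TRUE))
      mode <- sample(c("same", "reversal"), 1)
    })
    res <- intersect_concordant(a, b, mode)
    expect_equal(length(res$concordant) + length(res$discordant),
                 length(res$common))
    expect_length(intersect(res$concordant, res$discordant), 0)
    if (mode == "same") {
      expect_equal(length(res$common_down) + length(res$common_up),
                   length(res$concordant))
    }
  }
})

test_that("survival-by-drug contingency uses the one-sided Fisher test", {
  # 2x2 [[3,1],[1,3]] corresponds to the urn N=8, K=4, n=4, k=3
  all_degs <- paste0("g", 1:8)
  surv <- paste0("g", 1:4)
  drug <- c(paste0("g", 1:3), "g5")
  res <- survival_contingency(all_degs, surv, drug)
  expect_equal(res$table[1, 1], 3)
  expect_equal(res$p, 17 / 70, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$prop_survival_altered, 3 / 4)

  # the Fisher p equals the matching hypergeometric upper tail
  expect_equal(res$p, hypergeom_overrep(8, 4, 4, 3), tolerance = 1e-12)
  for (i in 1:10) {
    withr::with_seed(900 + i, {
      u <- paste0("g", 1:30)
      s <- sample(u, sample(5:15, 1))
      d <- sample(u, sample(5:15, 1))
    })
    expect_equal(survival_contingency(u, s, d)$p,
                 hypergeom_overrep(30, length(s), length(d),
                                   length(intersect(s, d))),
                 tolerance = 1e-12)
  }

  # drug-altered = everything: no enrichment possible
  expect_warning(full <- survival_contingency(all_degs, surv, all_degs),
                 "degenerate")
  expect_equal(full$p, 1)
  expect_warning(none <- survival_contingency(all_degs, character(0), drug),
                 "degenerate")
  expect_equal(none$p, 1)

  expect_error(survival_contingency(character(0), surv, drug), "empty")
  expect_error(survival_contingency(all_degs, "g99", drug), "g99")
})

test_that("regulator ranking counts pathway targets with deterministic ties", {
  tf <- tf_target_map(list(TF1 = c("g1", "g2", "g3"), TF2 = "g2"),
                      class = c("TF", "TF"))
  out <- rank_regulators(tf, c("g1", "g2"))
  expect_equal(out$regulator, c("TF1", "TF2"))
  expect_equal(out$target_count, c(2, 1))

  none <- rank_regulators(tf, character(0))
  expect_equal(none$target_count, c(0, 0))

  tie <- tf_target_map(list(ZTF = c("g1", "g2"), ATF = c("g1", "g2")))
  expect_equal(rank_regulators(tie, c("g1", "g2"))$regulator,
               c("ATF", "ZTF"))
})

test_that("candidate nomination applies all four evidence criteria", {
  cox <- data.frame(gene = c("R1", "R2", "R3"), beta = c(1, 1, -1),
                    se = 1, z = 2, p = c(0.01, 0.2, 0.01), hr = exp(c(1, 1, -1)),
                    direction = c("high_worse", "high_worse", "high_better"),
                    converged = TRUE)
  tumor <- deg_row(c("R1", "R2", "R3"), c("up", "up", "up"))
  drug <- deg_row(c("R1", "R2", "R3"), c("down", "down", "down"))

  out <- nominate_candidates(c("R1", "R2", "R3"), cox, tumor, drug)
  expect_equal(out$regulator, "R1")          # R2 fails Cox p, R3 fails HR>1
  expect_equal(out$tumor_direction, "up")
  expect_equal(out$drug_direction, "down")

  # regulator absent from an evidence table is excluded with a message
  expect_message(miss <- nominate_candidates(c("R1", "R9"), cox, tumor, drug),
                 "R9")
  expect_equal(miss$regulator, "R1")

  expect_equal(nrow(nominate_candidates(character(0), cox, tumor, drug)), 0)

  # output is a subset of the ranked input, order-stable
  ranked <- data.frame(regulator = c("R3", "R1", "R2"), class = "TF",
                       target_count = 3:1)
  sub <- nominate_candidates(ranked, cox, tumor, drug)
  expect_true(all(sub$regulator %in% ranked$regulator))
  expect_equal(sub$regulator, intersect(ranked$regulator, sub$regulator))
})
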