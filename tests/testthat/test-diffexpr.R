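test_that("pooled-variance t-test and fold change follow their definitions", {
  expr <- two_group_expr(list(
    flat = list(a = c(1, 2, 3), b = c(1, 2, 3)),
    up1  = list(a = c(4, 5, 6), b = c(5, 6, 7)),
    down = list(a = c(8, 8.5, 9), b = c(6, 6.5, 7))
  ))
  tb <- ttest_fold_change(expr, "grpA", "grpB")

  flat <- tb[tb$gene == "flat", ]
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$fc, 1)

  # +1 mean log2 difference is exactly a 2-fold change, direction up
  up <- tb[tb$gene == "up1", ]
  expect_equal(up$fc, 2)
  expect_equal(up$direction, "up")
  expect_equal(tb$direction[tb$gene == "down"], "down")

  # matches stats::t.test with pooled variance
  ref <- stats::t.test(c(5, 6, 7), c(4, 5, 6), var.equal = TRUE)
  expect_equal(up$p, ref$p.value)
  expect_equal(abs(up$statistic), abs(ref$statistic), ignore_attr = TRUE)
})

test_that("zero-variance genes with unequal means are flagged, not fatal", {
  expr <- two_group_expr(list(g = list(a = c(0, 0), b = c(1, 1))))
  expect_message(tb <- ttest_fold_change(expr, "grpA", "grpB"), "degenerate")
  expect_true(tb$degenerate)
  expect_true(is.na(tb$p))
  expect_false(call_degs(tb)$is_deg)
})

test_that("swapping group labels flips the statistic and keeps p", {
  withr::with_seed(21, {
    m <- matrix(rnorm(60, 8), 10, 6,
                dimnames = list(paste0("G", 1:10), paste0("s", 1:6)))
  })
  expr <- make_intensity(m)
  ab <- ttest_fold_change(expr, "a", "b")
  ba <- ttest_fold_change(expr, "b", "a")
  expect_equal(ab$p, ba$p)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$log2fc, -ba$log2fc)
})

test_that("probe collapse keeps the most significant probe with deterministic ties", {
  tb <- rbind(
    data.frame(gene = "p1", statistic = 2, p = 0.01, fdr = NA, fc = 1.8,
               log2fc = log2(1.8), direction = "up", degenerate = FALSE,
               is_deg = FALSE),
    data.frame(gene = "p2", statistic = 2, p = 0.03, fdr = NA, fc = 2.5,
               log2fc = log2(2.5), direction = "up", degenerate = FALSE,
               is_deg = FALSE)
  )
  map <- c(p1 = "GENE", p2 = "GENE")
  out <- collapse_probes(tb, map)
  expect_equal(nrow(out), 1)
  expect_equal(out$probe, "p1")
  expect_equal(out$p, 0.01)

  # single probe per gene: unchanged values
  one <- collapse_probes(tb, c(p1 = "G_A", p2 = "G_B"))
  expect_equal(nrow(one), 2)
  expect_setequal(one$gene, c("G_A", "G_B"))

  # p tie broken by larger |log2FC|, then lexicographic probe id
  tie <- tb
  tie$p <- 0.01
  out_tie <- collapse_probes(tie, map)
  expect_equal(out_tie$probe, "p2")
  tie$fc <- 2; tie$log2fc <- 1
  expect_equal(collapse_probes(tie, map)$probe, "p1")

  # unmapped probes dropped with a message
  expect_message(dropped <- collapse_probes(tb, c(p1 = "GENE")), "1 unmapped")
  expect_equal(nrow(dropped), 1)

  empty <- collapse_probes(tb[0, ], map)
  expect_equal(nrow(empty), 0)
})

test_that("DEG thresholds are inclusive on both p and fold change", {
  tb <- data.frame(
    gene = c("a", "b", "c", "d"),
    statistic = 1, p = c(0.04, 0.05, 0.04, 0.04), fdr = NA,
    fc = c(1.6, 1.5, 1.4, 1 / 1.5),
    log2fc = log2(c(1.6, 1.5, 1.4, 1 / 1.5)),
    direction = c("up", "up", "up", "down"),
    degenerate = FALSE, is_deg = FALSE
  )
  out <- call_degs(tb, p_max = 0.05, fc_min = 1.5)
  expect_equal(out$is_deg, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(call_degs(tb, fc_min = 0.9), "at least 1")

  # output invariant to gene order
  withr::with_seed(2, perm <- sample(nrow(tb)))
  out_perm <- call_degs(tb[perm, ], p_max = 0.05, fc_min = 1.5)
  expect_equal(out_perm$is_deg[order(perm)], out$is_deg)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  for (i in 1:200) {
    withr::with_seed(i, p <- runif(sample(1:30, 1)))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("count-based DE finds planted signals and nothing in duplicates", {
  sim <- simulate_cohort(n_tumor = 200, n_normal = 200, n_genes = 100,
                         de_fraction = 0.1, lfc_location = 2,
                         dispersion = 0.05, seed = 31)
  tb <- count_degs(sim$expr, "normal", "tumor")
  planted <- sim$truth$genes$gene[sim$truth$genes$lfc == 2]
  expect_true(all(tb$fdr[tb$gene %in% planted] <= 0.05))
  expect_true(all(tb$direction[tb$gene %in% planted] == "up"))

  # identical columns duplicated across groups: zero DEGs
  m <- matrix(rep(c(5L, 10L, 200L), 4), nrow = 3,
              dimnames = list(paste0("G", 1:3), paste0("s", 1:4)))
  dup <- expression_matrix(m, stats::setNames(c("a", "a", "b", "b"),
                                              colnames(m)),
                           flavor = "counts")
  expect_equal(sum(count_degs(dup, "a", "b")$is_deg), 0)

  # empty matrix in, empty table out
  e <- expression_matrix(matrix(integer(0), 0, 4,
                                dimnames = list(character(0),
                                                paste0("s", 1:4))),
                         stats::setNames(c("a", "a", "b", "b"),
                                         paste0("s", 1:4)),
                         flavor = "counts")
  expect_equal(nrow(count_degs(e, "a", "b")), 0)

  # zero-total-count sample is an input error naming the sample
  m0 <- m; m0[, 2] <- 0L
  z <- expression_matrix(m0, stats::setNames(c("a", "a", "b", "b"),
                                             colnames(m0)),
                         flavor = "counts")
  expect_error(count_degs(z, "a", "b"), "s2")
})
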