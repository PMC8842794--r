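test_that("generators are pure functions of their parameters and seed", {
  p1 <- simulate_perturbation(n_genes = 100, seed = 4)
  p2 <- simulate_perturbation(n_genes = 100, seed = 4)
  expect_identical(p1$expr$values, p2$expr$values)
  expect_identical(p1$truth$genes, p2$truth$genes)

  c1 <- simulate_cohort(n_tumor = 10, n_normal = 5, n_genes = 50, seed = 2)
  c2 <- simulate_cohort(n_tumor = 10, n_normal = 5, n_genes = 50, seed = 2)
  expect_identical(c1$expr$values, c2$expr$values)

  n1 <- simulate_network(n_nodes = 60, planted_module_size = 8, seed = 3)
  n2 <- simulate_network(n_nodes = 60, planted_module_size = 8, seed = 3)
  expect_identical(igraph::as_edgelist(n1$net), igraph::as_edgelist(n2$net))

  g1 <- simulate_gene_sets(paste0("G", 1:50), n_sets = 4,
                           set_size_range = c(5, 10), seed = 6)
  g2 <- simulate_gene_sets(paste0("G", 1:50), n_sets = 4,
                           set_size_range = c(5, 10), seed = 6)
  expect_identical(g1$sets$sets, g2$sets$sets)

  s1 <- simulate_survival(c1$expr, seed = 9)
  s2 <- simulate_survival(c1$expr, seed = 9)
  expect_identical(s1$time, s2$time)

  # generators restore the caller's random state
  withr::with_seed(1, {
    before <- .Random.seed
    simulate_perturbation(n_genes = 10, seed = 99)
    expect_identical(.Random.seed, before)
  })
})

test_that("perturbation generator plants the requested structure", {
  p <- simulate_perturbation(n_genes = 200, de_fraction = 0, seed = 1)
  expect_equal(sum(p$truth$genes$is_de), 0)

  p <- simulate_perturbation(n_genes = 1000, de_fraction = 0.2,
                             down_fraction = 0.76, seed = 2)
  expect_equal(sum(p$truth$genes$is_de), 200)
  frac_down <- mean(p$truth$genes$lfc[p$truth$genes$is_de] < 0)
  expect_gt(frac_down, 0.66)
  expect_lt(frac_down, 0.86)

  expect_error(simulate_perturbation(n_per_group = 1), "at least 2")
  expect_error(simulate_perturbation(de_fraction = 1.2), "0, 1")
})

test_that("cohort generator obeys its planted mean multiplier", {
  expect_error(simulate_cohort(dispersion = 0), "positive")
  expect_error(simulate_cohort(n_tumor = 1), "at least 2")

  # one gene with a planted 4x tumor multiplier: empirical mean ratio near 4
  sim <- simulate_cohort(n_tumor = 500, n_normal = 500, n_genes = 200,
                         de_fraction = 0.5, lfc_location = 2,
                         dispersion = 0.2, seed = 7)
  up <- which(sim$truth$genes$lfc == 2)
  tumor <- grepl("^tumor", colnames(sim$expr$values))
  ratios <- rowMeans(sim$expr$values[up, tumor]) /
    rowMeans(sim$expr$values[up, !tumor])
  # ratio of two NB means at n=500: spread well inside 20%
  expect_gt(stats::median(ratios), 4 * 0.8)
  expect_lt(stats::median(ratios), 4 * 1.2)
})

test_that("null cohort yields no false DE calls in most runs", {
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_cohort(n_tumor = 20, n_normal = 20, n_genes = 300,
                           de_fraction = 0, dispersion = 0.01, seed = seed)
    sum(count_degs(sim$expr, "normal", "tumor")$is_deg)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("survival generator censors and links hazards as declared", {
  expect_error(simulate_survival(matrix(1), base_hazard = 0), "positive")
  sim <- simulate_cohort(n_tumor = 30, n_normal = 30, n_genes = 20, seed = 1)

  # administrative censoring at time zero leaves no events for Cox
  cohort <- simulate_survival(sim$expr, censor_time = 0, seed = 2)
  expect_equal(sum(cohort$event), 0)
  expect_error(cox_univariate(cohort, rownames(sim$expr$values)[1]),
               "no events")

  # a strong positive beta is recovered with a positive sign
  signs <- vapply(1:20, function(seed) {
    coh <- simulate_cohort(n_tumor = 150, n_normal = 150, n_genes = 10,
                           de_fraction = 0, seed = seed)
    sc <- simulate_survival(coh$expr, risk_genes = c(G0001 = 1),
                            base_hazard = 0.1, seed = seed)
    sign(cox_univariate(sc, "G0001")$beta)
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})

test_that("network generator plants modules at the requested density", {
  plain <- simulate_network(n_nodes = 50, planted_module_size = 0, seed = 1)
  expect_length(plain$truth$module_nodes, 0)

  cliq <- simulate_network(n_nodes = 60, planted_module_size = 10,
                           planted_density = 1, seed = 2)
  sub <- igraph::induced_subgraph(cliq$net, cliq$truth$module_nodes)
  expect_equal(igraph::ecount(sub), choose(10, 2))
  expect_equal(lcc_size(cliq$net, cliq$truth$module_nodes), 10)

  expect_error(simulate_network(n_nodes = 5, planted_module_size = 6),
               "exceed")
  expect_warning(simulate_network(n_nodes = 30, edges_per_node = 5,
                                  planted_module_size = 5,
                                  planted_density = 0.05, seed = 3),
                 "background")
})

test_that("gene set generator honours enrichment fractions", {
  genes <- paste0("G", 1:200)
  de <- paste0("G", 1:50)
  sim <- simulate_gene_sets(genes, de, n_sets = 3,
                            set_size_range = c(5, 20),
                            enriched_sets = c(PLANTED = 1.0), seed = 4)
  expect_true(all(sim$sets$sets$PLANTED %in% de))
  expect_true(sim$truth$enriched_sets["PLANTED"])
  expect_false(any(sim$truth$enriched_sets[paste0("SET_", sprintf("%03d", 1:3))]))
  expect_error(simulate_gene_sets(genes, set_size_range = c(5, 300)),
               "universe")
  expect_error(simulate_gene_sets(genes, set_size_range = c(2, 10)),
               "5")
})

test_that("generated objects satisfy their type invariants across random draws", {
  for (i in 1:25) {
    withr::with_seed(1000 + i, {
      ng <- sample(20:80, 1)
      npg <- sample(2:5, 1)
      def <- runif(1)
    })
    p <- simulate_perturbation(n_genes = ng, n_per_group = npg,
                               de_fraction = def, seed = i)
    expect_s3_class(p$expr, "ExpressionMatrix")
    expect_equal(nrow(p$truth$genes), ng)
    expect_equal(sum(p$truth$genes$is_de), round(def * ng))
    expect_true(all(p$truth$genes$lfc[!p$truth$genes$is_de] == 0))

    cs <- simulate_cohort(n_tumor = npg + 2, n_normal = npg + 2,
                          n_genes = ng, de_fraction = def, seed = i)
    expect_true(all(cs$expr$values >= 0))
    expect_true(all(cs$expr$values == round(cs$expr$values)))

    nw <- suppressWarnings(
      simulate_network(n_nodes = ng, planted_module_size = min(10, ng),
                       planted_density = def, seed = i))
    expect_true(all(nw$truth$module_nodes %in% igraph::V(nw$net)$name))
    expect_equal(sum(igraph::which_loop(nw$net)), 0)
    expect_false(igraph::any_multiple(nw$net))
  }
})
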