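test_that("birth-death simulation is reproducible and conditioned on n", {
  t1 <- simulate_tree(1, 0, 5, seed = 1)
  t2 <- simulate_tree(1, 0, 5, seed = 1)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 5)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_tree(1, 2, 10, seed = 1), "death")
})

test_that("pure-birth root age matches the Yule expectation", {
  # E[age] = sum_{k=2..n} 1/(k b); Monte-Carlo check
  n <- 8; b <- 1
  ages <- vapply(1:400, function(i) {
    max(ape::node.depth.edgelength(simulate_tree(b, 0, n, seed = i)))
  }, 0)
  expected <- sum(1 / (b * (2:n)))
  expect_lt(abs(mean(ages) - expected) / expected, 0.1)
})

test_that("multi-regime Brownian motion has the regime-weighted covariance", {
  st <- star_tree(2, depth = 1)
  # sigma2 = 0 collapses to the root value
  x0 <- simulate_bm(three_tip_tree(), c(bg = 0), root_value = 3.3, seed = 1)
  expect_equal(unname(x0), rep(3.3, 3))
  # single regime, star tree depth 1: tip variance ~ sigma2 * t
  reps <- vapply(1:2000, function(i) {
    simulate_bm(st, c(bg = 1), seed = i)[[1]]
  }, 0)
  expect_lt(abs(var(reps) - 1), 0.12)

  # two regimes: sample covariance matches the regime-weighted vcv
  tr <- simulate_tree(1, 0, 6, seed = 7)
  shift_node <- 6 + 2L  # first non-root internal node
  shifts <- setNames(list("fast"), shift_node)
  sims <- sapply(1:1500, function(i) {
    simulate_bm(tr, c(bg = 1, fast = 10), shifts = shifts, seed = 1000 + i)
  })
  emp <- cov(t(sims))
  regime <- divpath:::paint_regimes(tr, shifts, "bg")
  tr_bg <- tr; tr_bg$edge.length <- ifelse(regime == "bg", tr$edge.length, 0)
  tr_f <- tr; tr_f$edge.length <- ifelse(regime == "fast", tr$edge.length, 0)
  theo <- ape::vcv.phylo(tr_bg) * 1 + ape::vcv.phylo(tr_f) * 10
  expect_lt(max(abs(emp - theo[rownames(emp), colnames(emp)])) /
              max(theo), 0.15)
})

test_that("DAG-generated data carry the generating coefficients", {
  tr <- simulate_tree(1, 0, 300, seed = 11)
  # single edge: PGLS slope near the coefficient
  dag1 <- causal_dag(c("X", "Y"), rbind(c("X", "Y")))
  d1 <- simulate_dag_data(tr, dag1, c("X->Y" = 0.8), seed = 12)
  f1 <- fit_pgls(d1, "Y", "X", tr)
  expect_lt(abs(f1$coefficients[["X"]] - 0.8), 0.15)

  # chain: partial coefficient of X in Z ~ X + Y is near zero
  dag2 <- causal_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  d2 <- simulate_dag_data(tr, dag2, c("X->Y" = 0.7, "Y->Z" = 0.7), seed = 13)
  f2 <- fit_pgls(d2, "Z", c("X", "Y"), tr)
  expect_lt(abs(f2$coefficients[["X"]]), 0.15)

  # all columns standardized
  expect_true(all(abs(vapply(d2[-1], mean, 0)) < 1e-8))
  expect_true(all(abs(vapply(d2[-1], sd, 0) - 1) < 1e-8))

  cyc <- list(nodes = c("A", "B"), edges = rbind(c("A", "B"), c("B", "A")))
  expect_error(causal_dag(cyc$nodes, cyc$edges), "cyclic")
})

test_that("chromosome simulation follows the chain's event structure", {
  tr <- simulate_tree(1, 0, 20, seed = 3)
  # zero rates: every tip keeps the root state
  tips0 <- simulate_chrom(tr, chrom_params(), root_state = 12, seed = 4)
  expect_true(all(tips0 == 12))
  expect_error(simulate_chrom(tr, chrom_params(), root_state = 0, seed = 1),
               "bounds")

  # gain-only chain on a star tree: mean increase ~ Poisson expectation
  st <- star_tree(400, depth = 2)
  tipsg <- simulate_chrom(st, chrom_params(lambda0 = 0.8), root_state = 5,
                          n_max = 200, seed = 5)
  expect_lt(abs(mean(tipsg - 5) - 0.8 * 2), 0.15)

  # determinism
  a <- simulate_chrom(tr, model1_params(), root_state = 10, seed = 9)
  b <- simulate_chrom(tr, model1_params(), root_state = 10, seed = 9)
  expect_identical(a, b)
})

test_that("fixture writer emits the documented plain-text artifacts", {
  ds <- simulate_dataset(n_tips = 20, seed = 2)
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "traits.csv",
                                               "config.yaml")))))
  tab <- read_trait_table(file.path(dir, "traits.csv"))
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_silent(validate_traits(tab, tree))
})
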