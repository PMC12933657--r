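test_that("basis sets have the textbook structure", {
  # complete DAG: empty basis set
  full <- causal_dag(c("A", "B", "C"),
                     rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(nrow(basis_set(full)), 0)

  # chain: exactly one claim, (X, Z | Y)
  chain <- causal_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  bs <- basis_set(chain)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$x, "X")
  expect_equal(bs$response, "Z")
  expect_equal(bs$conditioning, "Y")

  # size identity: C(k,2) - e claims
  for (ms in list(build_rate_models(), build_mean_models())) {
    for (m in ms$models) {
      k <- length(m$nodes)
      expect_equal(nrow(basis_set(m)), choose(k, 2) - nrow(m$edges))
    }
  }
})

test_that("every basis-set claim is d-separated in its DAG (brute force)", {
  # all DAGs of the 5- and 6-node enumeration groups, checked against an
  # exhaustive path-blocking oracle
  gs <- divpath:::ms_groups()
  models <- c(divpath:::build_group(gs$rates, "rates"),
              divpath:::build_group(gs$rates_chromnum, "rates_chromnum"))
  for (m in models) {
    bs <- basis_set(m)
    for (i in seq_len(nrow(bs))) {
      z <- if (nzchar(bs$conditioning[i])) {
        strsplit(bs$conditioning[i], ",")[[1]]
      } else character(0)
      expect_true(d_separated(m, bs$x[i], bs$response[i], z),
                  info = paste(m$id, bs$formula[i]))
    }
  }
})

test_that("Fisher's C and CICc match hand arithmetic", {
  expect_equal(fisher_c(numeric(0)), 0)
  expect_equal(fisher_c(c(1, 1)), 0)
  expect_equal(fisher_c(c(0.05, 0.5)), -2 * (log(0.05) + log(0.5)))
  expect_equal(fisher_c(c(0.05, 0.5)), 7.377, tolerance = 1e-3)
  expect_error(fisher_c(c(0.5, 0)), "degenerate")

  expect_equal(cicc(0, 0, 10), 0)
  expect_equal(cicc(10, 5, 20), 10 + 10 * 20 / 14)
  expect_equal(cicc(10, 5, 20), 24.2857, tolerance = 1e-4)
  expect_error(cicc(1, 5, 6), "overparameterized")
  expect_lt(abs(cicc(7, 3, 1e9) - (7 + 6)), 1e-6)
})

test_that("model-set fitting ranks, caches, and averages correctly", {
  tr <- simulate_tree(1, 0, 100, seed = 31)
  dag <- chain_dag()
  tab <- simulate_dag_data(tr, dag, c("RB4->R2n" = 0.7, "R2n->DI" = 0.7),
                           seed = 32)

  # single saturated model: C = 0, CICc = 2qn/(n-1-q)
  nodes <- c("RB4", "R2n", "DI")
  sat <- causal_dag(nodes, rbind(c("RB4", "R2n"), c("RB4", "DI"),
                                 c("R2n", "DI")))
  fit_sat <- fit_model_set(list(sat = sat), tab, tr)
  q <- 3 + 2
  expect_equal(fit_sat$ranking$C, 0)
  expect_equal(fit_sat$ranking$CICc, 2 * q * 100 / (100 - 1 - q))

  # duplicate DAGs: identical CICc, shared regressions deduplicated
  two <- list(a = chain_dag(), b = chain_dag())
  fit2 <- fit_model_set(two, tab, tr)
  expect_equal(fit2$ranking$CICc[1], fit2$ranking$CICc[2])
  expect_equal(fit2$n_unique_regressions, fit2$n_regressions / 2)

  # ranking invariant under model relabeling
  ms <- build_rate_models()
  f1 <- fit_model_set(ms, tab, tr)
  shuffled <- ms$models[rev(seq_along(ms$models))]
  f2 <- fit_model_set(shuffled, tab, tr)
  expect_equal(f1$ranking$model, f2$ranking$model)
  expect_equal(f1$ranking$CICc, f2$ranking$CICc)
})

test_that("full model averaging zero-imputes absent paths", {
  # synthetic ppa_fit with two equal-CICc models, path present in one
  tr <- simulate_tree(1, 0, 80, seed = 41)
  tab <- simulate_dag_data(tr, causal_dag(c("X", "Y"), rbind(c("X", "Y"))),
                           c("X->Y" = 0.4), seed = 42)
  m_edge <- causal_dag(c("X", "Y"), rbind(c("X", "Y")))
  m_null <- causal_dag(c("X", "Y"))
  fit <- fit_model_set(list(edge = m_edge, null = m_null), tab, tr)
  # force equal weights to isolate the zero-imputation arithmetic
  fit$ranking$delta <- c(0, 0)
  avg <- average_models(fit, cutoff = 2)
  beta_single <- divpath:::path_coefficients(m_edge, fit$table, tr)$coef
  expect_equal(avg$coefficients$coef[avg$coefficients$from == "X"],
               beta_single / 2, tolerance = 1e-10)

  # one model in the window: coefficients unchanged
  fit1 <- fit_model_set(list(edge = m_edge), tab, tr)
  avg1 <- average_models(fit1)
  expect_equal(avg1$coefficients$coef, beta_single, tolerance = 1e-12)

  # averaged coefficients shrink toward zero when a candidate lacks the path
  expect_lt(abs(avg$coefficients$coef[1]), abs(beta_single))
})

test_that("path_coefficients is exported via averaging and DOT output works", {
  tr <- simulate_tree(1, 0, 60, seed = 51)
  tab <- simulate_dag_data(tr, chain_dag(),
                           c("RB4->R2n" = 0.6, "R2n->DI" = 0.6), seed = 52)
  fit <- fit_model_set(list(chain = chain_dag()), tab, tr)
  avg <- average_models(fit)
  dot <- averaged_to_dot(avg)
  expect_match(dot, "RB4 -> R2n")
  expect_match(dot, "digraph")
})
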