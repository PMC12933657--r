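test_that("rate matrix has the documented structure", {
  Q0 <- build_rate_matrix(chrom_params(), 1, 10)
  expect_equal(max(abs(Q0)), 0)

  Q1 <- build_rate_matrix(chrom_params(lambda0 = 1), 2, 4)
  expect_equal(Q1["2", "3"], 1)
  expect_equal(Q1["3", "4"], 1)
  expect_equal(max(abs(Q1["4", ])), 0)  # no moves out of the top state

  # rows sum to zero for random parameters
  set.seed(8)
  for (i in 1:20) {
    p <- chrom_params(rho = runif(1, 0, 0.5), lambda0 = runif(1, 0, 3),
                      delta0 = runif(1, 0, 3), lambda1 = runif(1, 0, 0.2),
                      delta1 = runif(1, 0, 0.2))
    Q <- build_rate_matrix(p, 5, 40)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
  }
})

test_that("transition matrices are stochastic and pruning matches enumeration", {
  p <- chrom_params(rho = 0.3, lambda0 = 0.8, delta0 = 0.5,
                    lambda1 = 0.05, delta1 = 0.02)
  Q <- build_rate_matrix(p, 1, 8)
  op <- divpath:::make_tpm_op(Q)
  P <- vapply(1:8, function(j) {
    v <- numeric(8); v[j] <- 1
    as.vector(op$fn(1.3, v))
  }, numeric(8))  # columns j: P e_j, so t(P) rows are transition rows
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)

  # 3-tip exhaustive enumeration over internal-node states
  tree <- three_tip_tree()
  tips <- c(A = 4L, B = 5L, C = 3L)
  ll <- chrom_loglik(tree, tips, p, n_min = 1, n_max = 8,
                     root_prior = "uniform")
  Pm <- function(t) as.matrix(Matrix::expm(Q * t))
  P15 <- Pm(1.5); P1 <- Pm(1); P2 <- Pm(2)
  tot <- 0
  for (r in 1:8) for (v in 1:8) {
    tot <- tot + (1 / 8) * P15[r, v] * P1[v, 4] * P1[v, 5] * P2[r, 3]
  }
  expect_equal(ll, log(tot), tolerance = 1e-10)
})

test_that("zero-rate chain with invariant tips has log-likelihood zero", {
  tree <- three_tip_tree()
  ll <- chrom_loglik(tree, c(A = 5L, B = 5L, C = 5L), chrom_params(),
                     n_min = 1, n_max = 8)
  expect_equal(ll, 0)
  # and a tip unreachable without events is much less likely under tiny rates
  tiny <- chrom_params(lambda0 = 1e-6, delta0 = 1e-6)
  ll_inv <- chrom_loglik(tree, c(A = 5L, B = 5L, C = 5L), tiny,
                         n_min = 1, n_max = 8)
  ll_jump <- chrom_loglik(tree, c(A = 5L, B = 5L, C = 7L), tiny,
                          n_min = 1, n_max = 8)
  expect_lt(ll_jump, ll_inv - 10)
})

test_that("likelihood is invariant to child rotation", {
  p <- model1_params()
  tr <- simulate_tree(1, 0, 30, seed = 61)
  tips <- simulate_chrom(tr, p, root_state = 10, seed = 62)
  tr_rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(chrom_loglik(tr, tips, p),
               chrom_loglik(tr_rot, tips, p), tolerance = 1e-10)
})

test_that("tip dysploidy rates follow the fitted linear formula", {
  tr <- simulate_tree(1, 0, 25, seed = 63)
  tips <- simulate_chrom(tr, model1_params(), root_state = 10, seed = 64)
  fit <- structure(list(tree = tr, tip_states = tips,
                        regimes = list(bg = model1_params()),
                        tip_regime = setNames(rep("bg", 25), names(tips))),
                   class = "chrom_fit")
  sp <- names(tips)[1]
  n <- tips[[sp]]
  expect_equal(tip_dysploidy_rate(fit, sp)[[sp]],
               (2.035 + 0.062 * n) + (1.610 + 0.102 * n))
  expect_equal(tip_dysploidy_rate(fit, sp, component = "gain")[[sp]],
               2.035 + 0.062 * n)
  # zero-rate regime gives zero
  fit0 <- fit; fit0$regimes$bg <- chrom_params()
  expect_equal(unname(tip_dysploidy_rate(fit0, sp)), 0)
  # nondecreasing in n when both slopes are non-negative
  rates <- (2.035 + 0.062 * (5:40)) + (1.610 + 0.102 * (5:40))
  expect_true(all(diff(rates) >= 0))
  expect_error(tip_dysploidy_rate(fit, "nope"), "not in fit")
})

test_that("max_regimes = 1 forces a single regime", {
  tr <- simulate_tree(1, 0, 40, seed = 65)
  tips <- simulate_chrom(tr, model1_params(), root_state = 10, seed = 66)
  fit <- fit_chrom_model(tr, tips, allow_shifts = TRUE, max_regimes = 1,
                         n_starts = 1)
  expect_length(fit$regimes, 1)
  expect_length(fit$shift_nodes, 0)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * 5)
})

test_that("dysploidy baselines are recovered within their profile spread", {
  # single-regime simulations at 500 tips under the background parameters;
  # the baseline/slope trade-off makes individual estimates ridge-like, but
  # the median relative error of the baselines stays under 50%
  p1 <- model1_params()
  errs <- sapply(1:10, function(i) {
    tr <- simulate_tree(1, 0, 500, seed = 7000 + i)
    tips <- simulate_chrom(tr, p1, root_state = 10, seed = 7100 + i)
    f <- fit_chrom_model(tr, tips, allow_shifts = FALSE, n_starts = 1)
    c(abs(f$regimes$bg$lambda0 - p1$lambda0) / p1$lambda0,
      abs(f$regimes$bg$delta0 - p1$delta0) / p1$delta0)
  })
  expect_lt(median(errs[1, ]), 0.5)
  expect_lt(median(errs[2, ]), 0.5)
})
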