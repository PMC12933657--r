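test_that("rate function families behave at their landmarks", {
  expect_equal(eval_rate_fn("constant", c(c = 0.3), c(-5, 0, 7)),
               rep(0.3, 3))
  expect_equal(eval_rate_fn("sigmoid",
                            c(y0 = 0.1, y1 = 0.5, xmid = 2, r = 1), 2), 0.3)
  hump <- c(y0 = 0.1, y1 = 0.6, xmid = 1, s = 0.5)
  expect_equal(eval_rate_fn("hump", hump, 1), 0.6)
  expect_equal(eval_rate_fn("hump", hump, 100), 0.1, tolerance = 1e-6)
  expect_equal(eval_rate_fn("linear", c(a = 0.2, b = -1), 5), 0)  # clamped
})

test_that("constant-rate likelihood matches the birth-death closed form", {
  tree <- simulate_tree(1, 0.3, 20, seed = 11)
  lam <- 0.9; mu <- 0.3; s2 <- 1e-8; tip_sd <- 0.05
  tips <- setNames(rep(0, 20), tree$tip.label)
  ll <- quasse_loglik(tree, tips, quasse_const(lam, mu, s2),
                      grid = unit_grid(128), tip_sd = tip_sd,
                      check_boundary = FALSE)
  oracle <- bd_kernel_oracle(tree, lam, mu, s2, tip_sd)
  expect_lt(abs(ll - oracle) / abs(oracle), 1e-3)

  # Yule special case (mu = 0)
  ll_y <- quasse_loglik(tree, tips, quasse_const(0.8, 1e-12, s2),
                        grid = unit_grid(128), tip_sd = tip_sd,
                        check_boundary = FALSE)
  oracle_y <- bd_kernel_oracle(tree, 0.8, 0, s2, tip_sd)
  expect_lt(abs(ll_y - oracle_y) / abs(oracle_y), 1e-3)
})

test_that("extinction stays in [0,1], D stays non-negative", {
  tree <- simulate_tree(1, 0.4, 15, seed = 12)
  set.seed(13)
  tips <- setNames(rnorm(15, 0, 0.3), tree$tip.label)
  model <- quasse_model(
    list(family = "hump", params = c(y0 = 0.4, y1 = 1.2, xmid = 0, s = 0.3)),
    list(family = "sigmoid", params = c(y0 = 0.1, y1 = 0.5, xmid = 0, r = 0.2)),
    0.05)
  res <- quasse_loglik(tree, tips, model, details = TRUE,
                       check_boundary = FALSE)
  expect_true(all(res$E >= 0 & res$E <= 1))
  expect_true(all(res$D >= 0))
  expect_true(is.finite(res$logLik))
})

test_that("the likelihood self-converges under bin doubling", {
  tree <- simulate_tree(1, 0.2, 15, seed = 14)
  tips <- setNames(rep(0, 15), tree$tip.label)
  m <- quasse_const(0.8, 0.2, 1e-8)
  ll1 <- quasse_loglik(tree, tips, m, grid = unit_grid(128), tip_sd = 0.05,
                       check_boundary = FALSE)
  ll2 <- quasse_loglik(tree, tips, m, grid = unit_grid(256), tip_sd = 0.05,
                       check_boundary = FALSE)
  expect_lt(abs(ll2 - ll1), 1e-3)
})

test_that("the likelihood is invariant to child rotation", {
  tree <- simulate_tree(1, 0, 12, seed = 15)
  set.seed(16)
  tips <- setNames(rnorm(12, 0, 0.2), tree$tip.label)
  m <- quasse_model(
    list(family = "linear", params = c(a = 0.8, b = 0.3)),
    list(family = "constant", params = c(c = 0.1)), 0.02)
  tree_rot <- ape::rotateConstr(tree, rev(tree$tip.label))
  g <- quasse_grid(tips, tree, 0.02)
  expect_equal(quasse_loglik(tree, tips, m, grid = g, check_boundary = FALSE),
               quasse_loglik(tree_rot, tips, m, grid = g,
                             check_boundary = FALSE),
               tolerance = 1e-8)
})

test_that("a narrow grid is reported as such", {
  tree <- simulate_tree(1, 0, 12, seed = 17)
  set.seed(18)
  tips <- setNames(rnorm(12), tree$tip.label)
  tight <- list(x = seq(min(tips), max(tips), length.out = 64),
                dx = diff(range(tips)) / 64, n_bins = 64L)
  m <- quasse_const(0.8, 0.1, 0.5)  # strong diffusion pushes mass outward
  expect_error(quasse_loglik(tree, tips, m, grid = tight), "boundary|widen")
})

test_that("fit_quasse returns a ranked AIC table with consistent arithmetic", {
  tree <- simulate_tree(1, 0, 50, seed = 19)
  dag <- causal_dag("X")
  tips <- setNames(simulate_dag_data(tree, dag, seed = 20)$X, tree$tip.label)
  fit <- suppressWarnings(
    fit_quasse(tree, tips, lambda_families = "constant",
               mu_families = "constant", n_bins = 64, maxit = 150))
  expect_equal(nrow(fit$table), 1)
  expect_equal(fit$table$AIC, -2 * fit$table$logLik + 2 * fit$table$k)
  expect_equal(fit$table$model, "bm.constant.constant")
})
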