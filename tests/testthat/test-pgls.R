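test_that("PGLS equals OLS on a star tree and exact fits are exact", {
  st <- star_tree(30, depth = 1)
  set.seed(1)
  tab <- data.frame(species = st$tip.label, x = rnorm(30))
  tab$y <- 0.5 * tab$x + rnorm(30, 0, 0.5)
  fit <- fit_pgls(tab, "y", "x", st)
  ols <- lm(scale(y) ~ scale(x), data = tab)
  expect_equal(unname(fit$coefficients["x"]), unname(coef(ols)[2]),
               tolerance = 1e-8)

  # y = x exactly: slope 1, zero residual variance
  tab2 <- data.frame(species = st$tip.label, x = rnorm(30))
  tab2$y <- tab2$x
  fit2 <- fit_pgls(tab2, "y", "x", st)
  expect_equal(unname(fit2$coefficients["x"]), 1, tolerance = 1e-10)
  expect_lt(fit2$sigma2, 1e-16)
})

test_that("PGLS matches the textbook GLS formula on a random tree", {
  tr <- simulate_tree(1, 0, 10, seed = 5)
  set.seed(2)
  tab <- data.frame(species = tr$tip.label, x = rnorm(10), y = rnorm(10))
  fit <- fit_pgls(tab, "y", "x", tr)
  V <- phylo_vcv(tr)[tab$species, tab$species]
  Vi <- solve(V)
  X <- cbind(1, scale(tab$x)[, 1])
  y <- scale(tab$y)[, 1]
  beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-8)
  # standard errors from the explicit inverse
  df <- 10 - 2
  resid <- y - X %*% beta
  s2 <- as.numeric(t(resid) %*% Vi %*% resid) / df
  se <- sqrt(diag(solve(t(X) %*% Vi %*% X)) * s2)
  expect_equal(unname(fit$se), unname(se), tolerance = 1e-8)
})

test_that("fits are invariant to row permutations and reject bad designs", {
  tr <- simulate_tree(1, 0, 30, seed = 6)
  set.seed(3)
  tab <- data.frame(species = tr$tip.label, x = rnorm(30), y = rnorm(30))
  fit1 <- fit_pgls(tab, "y", "x", tr)
  perm <- sample(30)
  fit2 <- fit_pgls(tab[perm, ], "y", "x", tr)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)

  tab$z <- tab$x  # collinear
  expect_error(fit_pgls(tab, "y", c("x", "z"), tr), "singular|collinear")
  expect_error(fit_pgls(tab[1:3, ], "y", c("x", "z"), tr), "few")
})

test_that("type-I error of the slope test is near nominal under the null", {
  hits <- 0; n_rep <- 400
  for (i in seq_len(n_rep)) {
    tr <- simulate_tree(1, 0, 50, seed = 9000 + i)
    d <- simulate_dag_data(tr, causal_dag(c("X", "Y")), seed = 500 + i)
    f <- fit_pgls(d, "Y", "X", tr)
    if (f$p[["X"]] < 0.05) hits <- hits + 1
  }
  ci <- qnorm(0.999) * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(hits / n_rep - 0.05), ci + 0.01)
})

test_that("ML lambda shrinks toward zero for non-phylogenetic data", {
  tr <- simulate_tree(1, 0, 80, seed = 10)
  set.seed(4)
  tab <- data.frame(species = tr$tip.label, x = rnorm(80), y = rnorm(80))
  fit <- fit_pgls(tab, "y", "x", tr, lambda_mode = "ml")
  expect_lt(fit$lambda, 0.5)
})
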