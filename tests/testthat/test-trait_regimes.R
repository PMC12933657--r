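test_that("single-regime ML matches closed forms", {
  # star tree: sigma2 equals the ML sample variance scaled by depth
  st <- star_tree(40, depth = 2)
  set.seed(71)
  y <- setNames(rnorm(40, 5, sqrt(3 * 2)), st$tip.label)
  fit <- fit_bm_regimes(st, y)
  expect_equal(unname(fit$sigma2), mean((y - mean(y))^2) / 2,
               tolerance = 1e-4)

  # general tree: log-likelihood equals the REML-free GLS normal density
  tr <- simulate_tree(1, 0, 30, seed = 72)
  x <- simulate_bm(tr, c(bg = 2), root_value = 1, seed = 73)
  fit2 <- fit_bm_regimes(tr, x)
  V <- phylo_vcv(tr)[names(x), names(x)] * fit2$sigma2[[1]]
  mu <- fit2$root
  ll <- as.numeric(-0.5 * (30 * log(2 * pi) + determinant(V)$modulus +
                             t(x - mu) %*% solve(V) %*% (x - mu)))
  expect_equal(fit2$logLik, ll, tolerance = 1e-6)
})

test_that("single-regime data rarely trigger spurious shifts", {
  hits <- 0
  for (i in 1:25) {
    tr <- simulate_tree(1, 0, 80, seed = 700 + i)
    x <- simulate_bm(tr, c(bg = 1), seed = 800 + i)
    fit <- fit_bm_regimes(tr, x, max_shifts = 2)
    if (length(fit$shifts) == 0) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * 25 - 1e-9)
})

test_that("a strong two-regime signal is localized at the true node", {
  hits <- 0; n_rep <- 20
  for (i in seq_len(n_rep)) {
    tr <- simulate_tree(1, 0, 200, seed = 900 + i)
    cnt <- divpath:::n_desc_tips(tr)
    cands <- which(cnt >= 80 & cnt <= 120)
    cands <- cands[cands > 201]
    if (!length(cands)) next
    v <- cands[1]
    x <- simulate_bm(tr, c(bg = 1, fast = 25),
                     shifts = setNames(list("fast"), v), seed = 950 + i)
    fit <- fit_bm_regimes(tr, x, max_shifts = 2)
    found <- as.integer(names(fit$shifts))
    adjacent <- c(v, tr$edge[tr$edge[, 2] == v, 1], tr$edge[tr$edge[, 1] == v, 2])
    if (length(found) && any(found %in% adjacent)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("adding a shift never decreases the raw log-likelihood", {
  tr <- simulate_tree(1, 0, 60, seed = 75)
  x <- simulate_bm(tr, c(bg = 1), seed = 76)
  f0 <- fit_bm_regimes(tr, x, max_shifts = 0)
  cnt <- divpath:::n_desc_tips(tr)
  v <- which(cnt >= 15 & cnt <= 30)
  v <- v[v > 61][1]
  regime <- divpath:::paint_regimes(tr, setNames(list("r2"), v), "bg")
  mats <- divpath:::regime_path_matrices(tr, regime)
  f1 <- divpath:::fit_sigmas(setNames(x[tr$tip.label], tr$tip.label), mats)
  expect_gte(f1$logLik, f0$logLik - 1e-6)
})

test_that("tip rates map regimes onto species and join onto the table", {
  tr <- simulate_tree(1, 0, 50, seed = 77)
  x <- simulate_bm(tr, c(bg = 2), seed = 78)
  fit <- fit_bm_regimes(tr, x, max_shifts = 0)
  rates <- tip_trait_rate(fit)
  expect_equal(unname(rates), rep(unname(fit$sigma2[1]), 50))
  expect_error(tip_trait_rate(fit, "unknown_sp"), "unknown")

  tab <- data.frame(species = tr$tip.label, culm = unname(x))
  tab2 <- add_tip_rates(tab, tr, "culm", max_shifts = 0)
  expect_true("r_culm" %in% names(tab2))
  expect_equal(tab2$r_culm, unname(rates[tab2$species]))
})
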