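# Trait-dependent diversification over a discretized continuous trait:
# speciation lambda(x) and extinction mu(x) drawn from constant / linear /
# sigmoid / hump families, trait dynamics Brownian or Ornstein-Uhlenbeck,
# likelihood by propagating extinction and clade density functions along the
# tree with operator splitting (pointwise reaction + spectral diffusion).

#' Evaluate a rate function family
#'
#' Families: `constant` (`c`), `linear` (`a + b x`, clamped at zero),
#' `sigmoid` (`y0 + (y1-y0)/(1+exp((xmid-x)/r))`), `hump`
#' (`y0 + (y1-y0) exp(-(x-xmid)^2/(2 s^2))`).
#'
#' @param family One of `"constant"`, `"linear"`, `"sigmoid"`, `"hump"`.
#' @param params Named numeric vector with the family's parameters
#'   (`c`; `a`, `b`; `y0`, `y1`, `xmid`, `r`; `y0`, `y1`, `xmid`, `s`).
#' @param x Trait values.
#' @return Rates at `x` (non-negative).
#' @export
eval_rate_fn <- function(family, params, x) {
  p <- as.list(params)
  switch(family,
         constant = rep(p$c, length(x)),
         linear = pmax(0, p$a + p$b * x),
         sigmoid = p$y0 + (p$y1 - p$y0) / (1 + exp((p$xmid - x) / p$r)),
         hump = p$y0 + (p$y1 - p$y0) * exp(-(x - p$xmid)^2 / (2 * p$s^2)),
         stop("unknown rate family: ", family))
}

#' Discretization grid for the trait
#'
#' Cell-centred grid spanning the observed trait range padded on both sides
#' by at least `4 * sqrt(sigma2 * depth)` (four standard deviations of the
#' trait diffusion over the tree depth).
#'
#' @param tip_values Observed trait values.
#' @param tree The phylogeny (for its depth).
#' @param sigma2 Diffusion rate used to size the padding.
#' @param n_bins Number of cells (>= 64; default 128).
#' @return List with `x` (cell centres), `dx`, `n_bins`.
#' @export
quasse_grid <- function(tip_values, tree, sigma2, n_bins = 128) {
  if (n_bins < 64) stop("n_bins must be at least 64")
  depth <- max(ape::node.depth.edgelength(tree))
  pad <- max(4 * sqrt(sigma2 * depth), 1e-3 * diff(range(tip_values)), 1e-6)
  lo <- min(tip_values) - pad
  hi <- max(tip_values) + pad
  dx <- (hi - lo) / n_bins
  list(x = lo + (seq_len(n_bins) - 0.5) * dx, dx = dx, n_bins = n_bins)
}

#' Specify a trait-dependent diversification model
#'
#' @param lambda,mu Lists `list(family =, params =)` for speciation and
#'   extinction, see [eval_rate_fn()].
#' @param sigma2 Trait diffusion rate (trait-units^2/Myr), > 0.
#' @param drift `NULL` for Brownian motion, or `list(alpha =, theta =)` for
#'   an Ornstein-Uhlenbeck pull of strength alpha toward optimum theta.
#' @return A list of class `quasse_model`.
#' @export
quasse_model <- function(lambda, mu, sigma2, drift = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(drift) && drift$alpha < 0) stop("alpha must be >= 0")
  structure(list(lambda = lambda, mu = mu, sigma2 = sigma2, drift = drift),
            class = "quasse_model")
}

# Spectral propagator of the spatial operator: diffusion (sigma2/2) d2/dx2
# with reflecting boundaries plus upwinded OU advection alpha (theta - x)
# d/dx. Returns function(u, t) = expm(L t) u via eigendecomposition.
make_diffusion_op <- function(grid, sigma2, drift = NULL) {
  n <- grid$n_bins; dx <- grid$dx
  c2 <- sigma2 / (2 * dx^2)
  L <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (j > 1) L[j, j - 1] <- L[j, j - 1] + c2
    if (j < n) L[j, j + 1] <- L[j, j + 1] + c2
    L[j, j] <- L[j, j] - c2 * ((j > 1) + (j < n))
  }
  if (!is.null(drift) && drift$alpha > 0) {
    a <- drift$alpha * (drift$theta - grid$x)
    for (j in seq_len(n)) {
      if (a[j] > 0 && j < n) {
        L[j, j + 1] <- L[j, j + 1] + a[j] / dx
        L[j, j] <- L[j, j] - a[j] / dx
      } else if (a[j] < 0 && j > 1) {
        L[j, j - 1] <- L[j, j - 1] - a[j] / dx
        L[j, j] <- L[j, j] + a[j] / dx
      }
    }
  }
  eg <- eigen(L)
  V <- eg$vectors; lam <- eg$values
  Vi <- solve(V)
  function(u, t) {
    out <- Re(V %*% (exp(lam * t) * (Vi %*% u)))
    pmax(out, 0)
  }
}

# One reaction step (RK4, pointwise in x) for the coupled system
#   dE/dt = mu - (lambda+mu) E + lambda E^2
#   dD/dt = -(lambda+mu) D + 2 lambda E D
react_rk4 <- function(E, D, lam, mu, dt) {
  fE <- function(E) mu - (lam + mu) * E + lam * E^2
  fD <- function(E, D) -(lam + mu) * D + 2 * lam * E * D
  k1E <- fE(E);               k1D <- fD(E, D)
  k2E <- fE(E + dt / 2 * k1E); k2D <- fD(E + dt / 2 * k1E, D + dt / 2 * k1D)
  k3E <- fE(E + dt / 2 * k2E); k3D <- fD(E + dt / 2 * k2E, D + dt / 2 * k2D)
  k4E <- fE(E + dt * k3E);     k4D <- fD(E + dt * k3E, D + dt * k3D)
  E2 <- E + dt / 6 * (k1E + 2 * k2E + 2 * k3E + k4E)
  D2 <- D + dt / 6 * (k1D + 2 * k2D + 2 * k3D + k4D)
  list(E = pmin(pmax(E2, 0), 1), D = pmax(D2, 0))
}

#' Trait-dependent diversification log-likelihood
#'
#' Propagates the extinction function E(x, t) and per-clade density D(x, t)
#' from the tips to the root: within branches by operator splitting
#' (pointwise reaction for the birth-death terms, spectral propagation of
#' the diffusion/advection operator); at nodes D <- D_left D_right
#' lambda(x); at the root D is integrated against a weighting density and,
#' by default, conditioned on survival of the two root lineages.
#'
#' @param tree Ultrametric `phylo` object.
#' @param tip_values Named numeric vector of trait values.
#' @param model A [quasse_model()].
#' @param grid A [quasse_grid()]; default built from the data and model.
#' @param tip_sd Standard deviation of the Gaussian kernel initializing each
#'   tip's D (measurement scale); default one cell width.
#' @param root `"obs"` (weight by the root D, default) or `"flat"`.
#' @param condition_surv Condition on survival (default `TRUE`).
#' @param dt_target Time-step target; each branch uses at least two steps of
#'   length at most this (default depth/100).
#' @param check_boundary Error if more than 1% of the root density mass sits
#'   in the outermost cells (grid too narrow). Default `TRUE`.
#' @param details Return the per-node E and D functions alongside the
#'   log-likelihood (default `FALSE`).
#' @return Log-likelihood (scalar), or a list when `details = TRUE`.
#' @export
quasse_loglik <- function(tree, tip_values, model, grid = NULL,
                          tip_sd = NULL, root = c("obs", "flat"),
                          condition_surv = TRUE, dt_target = NULL,
                          check_boundary = TRUE, details = FALSE) {
  root <- match.arg(root)
  tip_values <- tip_values[tree$tip.label]
  if (anyNA(tip_values)) stop("tip_values must cover every tip")
  if (is.null(grid)) grid <- quasse_grid(tip_values, tree, model$sigma2)
  x <- grid$x; dx <- grid$dx; nb <- grid$n_bins
  if (is.null(tip_sd)) tip_sd <- dx
  depth <- max(ape::node.depth.edgelength(tree))
  if (is.null(dt_target)) dt_target <- depth / 100
  lam <- eval_rate_fn(model$lambda$family, model$lambda$params, x)
  mu <- eval_rate_fn(model$mu$family, model$mu$params, x)
  if (any(lam < 0) || any(mu < 0)) stop("negative rates on the grid")
  diffop <- make_diffusion_op(grid, model$sigma2, model$drift)

  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  D <- matrix(0, nb, n_node)
  E <- matrix(0, nb, n_node)
  logsc <- numeric(n_node)
  if (check_boundary) {
    lo <- x[1] - dx / 2; hi <- x[nb] + dx / 2
    near <- tip_values < lo + 2 * tip_sd | tip_values > hi - 2 * tip_sd
    if (any(near)) {
      stop("tip values within 2 tip_sd of the grid boundary (",
           paste(names(tip_values)[near], collapse = ", "),
           "); widen the grid padding")
    }
  }
  for (i in seq_len(n_tip)) {
    k <- exp(-(x - tip_values[i])^2 / (2 * tip_sd^2))
    D[, i] <- k / (sum(k) * dx)
  }
  prop_branch <- function(Ev, Dv, len) {
    n_steps <- max(2L, ceiling(len / dt_target))
    dt <- len / n_steps
    for (s in seq_len(n_steps)) {
      r <- react_rk4(Ev, Dv, lam, mu, dt)
      Ev <- diffop(r$E, dt)
      Ev <- pmin(Ev, 1)
      Dv <- diffop(r$D, dt)
    }
    list(E = Ev, D = Dv)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  done <- logical(n_node)
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]; child <- po$edge[k, 2]
    up <- prop_branch(E[, child], D[, child], po$edge.length[k])
    mx <- max(up$D)
    if (mx <= 0) return(-Inf)
    m <- up$D / mx
    lsc <- logsc[child] + log(mx)
    if (!done[parent]) {
      D[, parent] <- m
      E[, parent] <- up$E
      logsc[parent] <- lsc
      done[parent] <- TRUE
    } else {
      D[, parent] <- D[, parent] * m * lam
      E[, parent] <- (E[, parent] + up$E) / 2  # identical up to numerics
      logsc[parent] <- logsc[parent] + lsc
      mx2 <- max(D[, parent])
      if (mx2 <= 0) return(-Inf)
      D[, parent] <- D[, parent] / mx2
      logsc[parent] <- logsc[parent] + log(mx2)
    }
  }
  rt <- n_tip + 1L
  d_root <- D[, rt]; e_root <- E[, rt]
  root_p <- if (root == "obs") {
    s <- sum(d_root) * dx
    if (s <= 0) return(-Inf)
    d_root / s
  } else rep(1 / (nb * dx), nb)
  if (check_boundary) {
    mass <- root_p / sum(root_p)
    if (sum(mass[c(1, 2, nb - 1, nb)]) > 0.01) {
      stop("density mass at the grid boundary exceeds 1%; widen the grid padding")
    }
  }
  ll <- log(sum(root_p * d_root) * dx) + logsc[rt]
  if (condition_surv) {
    ll <- ll - log(sum(root_p * lam * (1 - e_root)^2) * dx)
  }
  if (details) {
    return(list(logLik = ll, E = E, D = D, grid = grid, root_p = root_p))
  }
  ll
}

# parameter transforms per family for unconstrained optimization
quasse_family_info <- function(family, y_scale, x_range) {
  switch(family,
    constant = list(
      n = 1,
      start = c(c = y_scale),
      pack = function(p) log(p),
      unpack = function(v) c(c = exp(v[1]))),
    linear = list(
      n = 2,
      start = c(a = y_scale, b = 0),
      pack = function(p) c(log(p[["a"]]), p[["b"]]),
      unpack = function(v) c(a = exp(v[1]), b = v[2])),
    sigmoid = list(
      n = 4,
      start = c(y0 = y_scale * 0.5, y1 = y_scale * 1.5,
                xmid = mean(x_range), r = diff(x_range) / 10),
      pack = function(p) c(log(p[["y0"]]), log(p[["y1"]]), p[["xmid"]],
                           log(p[["r"]])),
      unpack = function(v) c(y0 = exp(v[1]), y1 = exp(v[2]), xmid = v[3],
                             r = exp(v[4]))),
    hump = list(
      n = 4,
      start = c(y0 = y_scale * 0.5, y1 = y_scale * 1.5,
                xmid = mean(x_range), s = diff(x_range) / 6),
      pack = function(p) c(log(p[["y0"]]), log(p[["y1"]]), p[["xmid"]],
                           log(p[["s"]])),
      unpack = function(v) c(y0 = exp(v[1]), y1 = exp(v[2]), xmid = v[3],
                             s = exp(v[4]))),
    stop("unknown rate family: ", family))
}

#' Fit trait-dependent diversification models and rank them by AIC
#'
#' Optimizes every combination of speciation family x extinction family x
#' trait dynamics (Brownian or Ornstein-Uhlenbeck) and returns the AIC
#' table. Each model is optimized by Nelder-Mead on transformed parameters
#' from heuristic starting values (birth-death yields the rate scale).
#'
#' @param tree Ultrametric `phylo` object (a warning is issued below 50
#'   tips).
#' @param tip_values Named trait vector.
#' @param lambda_families,mu_families Families to try (default all four).
#' @param drift `"bm"`, `"ou"`, or both.
#' @param n_bins Grid size (default 128).
#' @param maxit Optimizer iterations per model (default 300).
#' @param ... Passed to [quasse_loglik()].
#' @return Object of class `quasse_fit`: `$table` (family pair, k, logLik,
#'   AIC, dAIC) ranked by AIC, and `$models` (fitted [quasse_model()]s).
#' @export
fit_quasse <- function(tree, tip_values,
                       lambda_families = c("constant", "linear", "sigmoid", "hump"),
                       mu_families = c("constant", "linear", "sigmoid", "hump"),
                       drift = "bm", n_bins = 128, maxit = 300, ...) {
  if (length(tree$tip.label) < 50) {
    warning("fewer than 50 tips; trait-dependent rate estimates will be weak")
  }
  tip_values <- tip_values[tree$tip.label]
  depth <- max(ape::node.depth.edgelength(tree))
  n_tip <- length(tree$tip.label)
  y_scale <- max((log(n_tip) - log(2)) / depth, 0.01)  # crude Yule rate
  s2_start <- max(var(tip_values) / depth, 1e-6)
  x_range <- range(tip_values)
  results <- list(); models <- list()
  for (lf in lambda_families) for (mf in mu_families) for (dr in drift) {
    li <- quasse_family_info(lf, y_scale, x_range)
    mi <- quasse_family_info(mf, y_scale * 0.3, x_range)
    k <- li$n + mi$n + 1 + if (dr == "ou") 2 else 0
    unpack_model <- function(v) {
      lp <- li$unpack(v[seq_len(li$n)])
      mp <- mi$unpack(v[li$n + seq_len(mi$n)])
      s2 <- exp(v[li$n + mi$n + 1])
      dft <- if (dr == "ou") {
        list(alpha = exp(v[li$n + mi$n + 2]), theta = v[li$n + mi$n + 3])
      } else NULL
      quasse_model(list(family = lf, params = lp),
                   list(family = mf, params = mp), s2, dft)
    }
    v0 <- c(li$pack(li$start), mi$pack(mi$start), log(s2_start),
            if (dr == "ou") c(log(0.1), mean(x_range)))
    grid <- quasse_grid(tip_values, tree, s2_start * 4, n_bins = n_bins)
    obj <- function(v) {
      m <- tryCatch(unpack_model(v), error = function(e) NULL)
      if (is.null(m)) return(1e10)
      ll <- tryCatch(
        quasse_loglik(tree, tip_values, m, grid = grid,
                      check_boundary = FALSE, ...),
        error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    opt <- optim(v0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit))
    nm <- paste(dr, lf, mf, sep = ".")
    if (opt$value >= 1e10) {
      results[[nm]] <- data.frame(model = nm, k = k, logLik = NA_real_,
                                  AIC = NA_real_, converged = FALSE)
      next
    }
    results[[nm]] <- data.frame(model = nm, k = k, logLik = -opt$value,
                                AIC = 2 * opt$value + 2 * k,
                                converged = opt$convergence == 0)
    models[[nm]] <- unpack_model(opt$par)
  }
  tab <- do.call(rbind, results)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  structure(list(table = tab, models = models), class = "quasse_fit")
}

#' @export
print.quasse_fit <- function(x, ...) {
  cat("Trait-dependent diversification fits:\n")
  print(x$table, digits = 5)
  invisible(x)
}
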