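# Multi-regime Brownian motion for continuous traits: maximum likelihood
# with greedy AICc-selected rate shifts, yielding the per-tip evolutionary
# rates consumed by the path analyses.

# Per-regime shared-path matrices: T_r[i, j] = path length shared by tips i
# and j that lies in regime r. The trait covariance is sum_r sigma2_r * T_r.
regime_path_matrices <- function(tree, regime) {
  n_tip <- length(tree$tip.label)
  regs <- unique(regime)
  mats <- lapply(setNames(regs, regs), function(r) {
    tr <- tree
    tr$edge.length <- ifelse(regime == r, tree$edge.length, 0)
    ape::vcv.phylo(tr)
  })
  mats
}

bm_regime_loglik <- function(y, mats, sigma2) {
  V <- Reduce(`+`, Map(function(m, s) m * s, mats, sigma2[names(mats)]))
  n <- length(y)
  R <- tryCatch(chol(V + diag(1e-10, n)), error = function(e) NULL)
  if (is.null(R)) return(list(logLik = -Inf))
  one <- rep(1, n)
  ow <- backsolve(R, one, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  mu <- sum(ow * yw) / sum(ow * ow)   # GLS root state
  rw <- yw - mu * ow
  rss <- sum(rw^2)
  logdet <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * log(2 * pi) + logdet + rss)
  list(logLik = ll, root = mu)
}

fit_sigmas <- function(y, mats, start = NULL) {
  k <- length(mats)
  if (is.null(start)) start <- rep(log(var(y) / max(diag(Reduce(`+`, mats)))), k)
  obj <- function(ls) {
    ll <- bm_regime_loglik(y, mats, setNames(exp(ls), names(mats)))$logLik
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  o <- optim(start, obj, method = "L-BFGS-B", lower = rep(-25, k),
             upper = rep(15, k), control = list(maxit = 200))
  sig <- setNames(exp(o$par), names(mats))
  res <- bm_regime_loglik(y, mats, sig)
  list(sigma2 = sig, logLik = res$logLik, root = res$root)
}

aicc <- function(logLik, k, n) {
  -2 * logLik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# Selection score for the greedy shift search: AICc for the continuous
# parameters plus a code-length penalty of 2 log(m) per shift for the
# discrete shift location, chosen among m candidate nodes. Without this
# multiplicity term the maximum over candidates of the likelihood gain
# exceeds the plain one-parameter AICc penalty under the null in most
# datasets, and spurious shifts are selected freely.
shift_score <- function(logLik, n_shifts, n, n_candidates) {
  aicc(logLik, n_shifts + 2, n) +
    2 * n_shifts * log(max(n_candidates, 2))
}

#' Fit multi-regime Brownian motion to a continuous trait
#'
#' Single-regime Brownian motion is fitted by maximum likelihood (rate and
#' root state); shifts in the rate sigma^2 are then added greedily at
#' internal nodes with at least `min_clade` descendant tips (the shift
#' covers the stem branch and subtree). A candidate shift is kept only if
#' it improves the selection score (AICc plus a 2 log m code-length term
#' for the shift location among m candidates) and clears a
#' Bonferroni-corrected likelihood-ratio test, so that maximizing over
#' many candidate nodes does not manufacture shifts. The search stops at
#' `max_shifts` or when no candidate qualifies.
#'
#' @param tree A `phylo` object (>= 10 tips).
#' @param x Named numeric vector of tip trait values.
#' @param max_shifts Maximum number of rate shifts (default 5).
#' @param min_clade Minimum clade size for a shift (default 10).
#' @return An object of class `bm_regimes`: shift nodes, per-regime sigma^2
#'   (trait-units^2/Myr), root value, log-likelihood, AICc, and per-tip
#'   regime assignment.
#' @export
fit_bm_regimes <- function(tree, x, max_shifts = 5, min_clade = 10) {
  if (length(tree$tip.label) < 10) stop("need at least 10 tips")
  x <- x[tree$tip.label]
  if (anyNA(x) || any(!is.finite(x))) stop("trait values must be finite for every tip")
  if (var(x) == 0) {
    warning("zero trait variance; returning a single regime at the lower bound")
    return(structure(list(tree = tree, shifts = list(),
                          sigma2 = c(bg = exp(-25)), root = x[[1]],
                          logLik = NA_real_, AICc = NA_real_,
                          tip_regime = setNames(rep("bg", length(x)), names(x))),
                     class = "bm_regimes"))
  }
  shifts <- list()
  regime <- paint_regimes(tree, shifts, "bg")
  mats <- regime_path_matrices(tree, regime)
  fit <- fit_sigmas(x, mats)
  n <- length(x)
  cnt <- n_desc_tips(tree)
  n_tip <- length(tree$tip.label)
  candidates <- setdiff(which(cnt >= min_clade), c(seq_len(n_tip), n_tip + 1L))
  m_cand <- length(candidates)
  best_score <- shift_score(fit$logLik, 0, n, m_cand)
  while (length(shifts) < max_shifts) {
    open <- setdiff(candidates, as.integer(names(shifts)))
    best_cand <- NULL
    for (v in open) {
      trial <- c(shifts, setNames(list(paste0("regime_", v)), as.character(v)))
      regime_t <- paint_regimes(tree, trial, "bg")
      if (length(unique(regime_t)) != length(shifts) + 2) next  # swallowed regime
      mats_t <- regime_path_matrices(tree, regime_t)
      fit_t <- fit_sigmas(x, mats_t)
      a <- shift_score(fit_t$logLik, length(shifts) + 1, n, m_cand)
      if (is.null(best_cand) || a < best_cand$score) {
        best_cand <- list(node = v, score = a, fit = fit_t, shifts = trial)
      }
    }
    if (is.null(best_cand) || best_cand$score >= best_score) break
    # sequential-testing gate: the winning candidate must clear a
    # Bonferroni-corrected likelihood-ratio test (df = 1, family-wise 1%)
    # so that maximizing over candidates does not manufacture shifts
    lrt <- 2 * (best_cand$fit$logLik - fit$logLik)
    if (lrt < qchisq(1 - 0.01 / length(open), df = 1)) break
    shifts <- best_cand$shifts
    fit <- best_cand$fit
    best_score <- best_cand$score
  }
  regime <- paint_regimes(tree, shifts, "bg")
  tip_edge <- match(seq_len(n_tip), tree$edge[, 2])
  tip_regime <- setNames(regime[tip_edge], tree$tip.label)
  structure(list(tree = tree, shifts = shifts, sigma2 = fit$sigma2,
                 root = fit$root, logLik = fit$logLik,
                 AICc = aicc(fit$logLik, length(shifts) + 2, n),
                 score = best_score, tip_regime = tip_regime),
            class = "bm_regimes")
}

#' @export
print.bm_regimes <- function(x, ...) {
  cat("Multi-regime BM:", length(x$sigma2), "regime(s),",
      sprintf("logLik = %.3f, AICc = %.3f\n", x$logLik, x$AICc))
  print(round(x$sigma2, 5))
  if (length(x$shifts)) {
    cat("shifts at nodes:", paste(names(x$shifts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evolutionary rate at a species' terminal branch
#'
#' The sigma^2 of the regime governing the tip's terminal branch.
#'
#' @param model A `bm_regimes` fit.
#' @param species Species name(s); default all tips.
#' @return Named numeric vector of rates.
#' @export
tip_trait_rate <- function(model, species = NULL) {
  if (is.null(species)) species <- names(model$tip_regime)
  missing_sp <- setdiff(species, names(model$tip_regime))
  if (length(missing_sp)) {
    stop("unknown species: ", paste(missing_sp, collapse = ", "))
  }
  setNames(model$sigma2[model$tip_regime[species]], species)
}

#' Compute tip evolutionary-rate columns for several traits
#'
#' Runs [fit_bm_regimes()] per column and joins the per-tip rates back onto
#' the trait table as `r_<column>` variables.
#'
#' @param table Trait table with a `species` column.
#' @param tree A `phylo` object.
#' @param columns Trait columns to process.
#' @param rate_names Optional output names (default `r_<column>`).
#' @param ... Passed to [fit_bm_regimes()].
#' @return The table with appended rate columns; fits attached as the
#'   `"fits"` attribute.
#' @export
add_tip_rates <- function(table, tree, columns, rate_names = NULL, ...) {
  if (is.null(rate_names)) rate_names <- paste0("r_", columns)
  fits <- list()
  for (i in seq_along(columns)) {
    x <- setNames(table[[columns[i]]], table$species)
    fit <- fit_bm_regimes(tree, x, ...)
    fits[[columns[i]]] <- fit
    table[[rate_names[i]]] <- unname(tip_trait_rate(fit)[table$species])
  }
  attr(table, "fits") <- fits
  table
}
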