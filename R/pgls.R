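# Phylogenetic generalized least squares: the atomic regression unit behind
# every d-separation test and path coefficient in the path analyses.

#' Z-score columns of a trait table
#'
#' Ordinary (non-phylogenetic) standardization; path coefficients on z-scored
#' variables are the standardized coefficients bounded in [-1, 1] that the
#' path analyses report.
#'
#' @param table Data.frame with a `species` column.
#' @param columns Columns to scale; default all numeric columns.
#' @return The table with scaled columns.
#' @export
standardize_traits <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  for (col in columns) {
    v <- table[[col]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop("column '", col, "' has zero variance")
    table[[col]] <- (v - mean(v)) / s
  }
  table
}

# Cholesky-based GLS context for one tree: precomputes the factor of the
# (lambda-scaled) Brownian covariance so that many regressions on the same
# tree reuse it. Returns a function(y, X) giving the GLS fit.
pgls_context <- function(tree, species, lambda = 1) {
  V <- phylo_vcv(tree)
  if (!all(species %in% rownames(V))) {
    stop("species missing from tree: ",
         paste(setdiff(species, rownames(V)), collapse = ", "))
  }
  V <- V[species, species]
  if (lambda != 1) {
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  R <- chol(V)
  # whitening: solve(t(R), .) maps GLS to OLS
  function(y, X) {
    yw <- backsolve(R, y, transpose = TRUE)
    Xw <- backsolve(R, X, transpose = TRUE)
    qr_ <- qr(Xw)
    if (qr_$rank < ncol(Xw)) {
      stop("singular design; collinear columns: ",
           paste(colnames(X)[qr_$pivot[seq(qr_$rank + 1, ncol(Xw))]],
                 collapse = ", "))
    }
    beta <- qr.coef(qr_, yw)
    resid <- yw - Xw %*% beta
    n <- length(y); p <- ncol(X)
    df <- n - p
    rss <- sum(resid^2)
    sigma2_ml <- rss / n
    XtX_inv <- solve(crossprod(Xw))
    se <- sqrt(diag(XtX_inv) * rss / df)
    tval <- beta / se
    pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    logdetV <- 2 * sum(log(diag(R)))
    ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
    list(coefficients = beta, se = se, t = tval, p = pval, df = df,
         sigma2 = sigma2_ml, logLik = ll)
  }
}

#' Fit a phylogenetic regression (PGLS)
#'
#' Generalized least squares with residual covariance proportional to the
#' (optionally lambda-scaled) Brownian covariance of the tree. Variables are
#' z-scored before fitting so coefficients are standardized. With
#' `lambda_mode = "ml"` Pagel's lambda is profiled over a grid plus local
#' refinement; the default fixes lambda at 1 (pure Brownian residuals), which
#' keeps model-set regression counts deterministic.
#'
#' @param table Trait table with a `species` column.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names (may be
#'   empty: intercept-only fit).
#' @param tree A `phylo` object covering the table's species.
#' @param lambda_mode `"fixed1"` (default) or `"ml"`.
#' @param standardize Z-score variables first (default `TRUE`).
#' @return An object of class `pgls_fit`: coefficients, standard errors, t
#'   and p values, residual df, log-likelihood, lambda.
#' @export
fit_pgls <- function(table, response, predictors, tree,
                     lambda_mode = c("fixed1", "ml"), standardize = TRUE) {
  lambda_mode <- match.arg(lambda_mode)
  vars <- c(response, predictors)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  if (n <= length(predictors) + 2) stop("too few species for this design")
  if (standardize) table <- standardize_traits(table, vars)
  y <- table[[response]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, predictors, drop = FALSE]))
  fit_at <- function(lam) {
    ctx <- pgls_context(tree, table$species, lambda = lam)
    ctx(y, X)
  }
  if (lambda_mode == "fixed1") {
    lambda <- 1
    fit <- fit_at(1)
  } else {
    grid <- seq(0, 1, by = 0.1)
    lls <- vapply(grid, function(l) fit_at(l)$logLik, 0)
    l0 <- grid[which.max(lls)]
    opt <- optimize(function(l) fit_at(l)$logLik,
                    lower = max(0, l0 - 0.1), upper = min(1, l0 + 0.1),
                    maximum = TRUE)
    lambda <- opt$maximum
    fit <- fit_at(lambda)
  }
  structure(list(response = response, predictors = predictors,
                 coefficients = setNames(as.vector(fit$coefficients),
                                         colnames(X)),
                 se = setNames(as.vector(fit$se), colnames(X)),
                 t = setNames(as.vector(fit$t), colnames(X)),
                 p = setNames(as.vector(fit$p), colnames(X)),
                 df = fit$df, logLik = fit$logLik, lambda = lambda,
                 sigma2 = fit$sigma2, n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS:", x$response, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
      sprintf(" (n=%d, lambda=%.3g, logLik=%.3f)\n", x$n, x$lambda, x$logLik))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}
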