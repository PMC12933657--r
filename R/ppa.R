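# Phylogenetic path analysis: d-separation tests, Fisher's C, CICc ranking
# and full model averaging over a candidate set of causal models.

#' Fisher's C statistic
#'
#' \eqn{C = -2 \sum \ln p} over the p-values of a model's d-separation tests.
#' Under the causal model, C is chi-squared distributed with 2k degrees of
#' freedom (k = number of claims).
#'
#' @param p_values Numeric vector of p-values in (0, 1]. May be empty.
#' @return C (0 for an empty vector).
#' @export
fisher_c <- function(p_values) {
  if (!length(p_values)) return(0)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]; a zero p-value indicates a ",
         "numerically degenerate regression")
  }
  -2 * sum(log(p_values))
}

#' C-statistic information criterion with small-sample correction
#'
#' \eqn{CICc = C + 2 q n / (n - 1 - q)} where q is the number of model
#' parameters and n the number of species.
#'
#' @param C Fisher's C.
#' @param q Parameter count of the causal model.
#' @param n Sample size (species).
#' @return The CICc value.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) stop("n must exceed q + 1; model is overparameterized")
  C + 2 * q * n / (n - 1 - q)
}

# Parameter count for CICc: one per directed edge plus one intercept per
# endogenous node, matching the counting of the reference PPA implementation.
dag_q <- function(dag) {
  nrow(dag$edges) + length(unique(dag$edges[, 2]))
}

#' Fit and rank a set of causal models by CICc
#'
#' Every model's d-separation claims are tested with one PGLS each (the
#' claim's later variable regressed on the earlier plus the union of their
#' parents; the tested coefficient is the earlier variable's). Regressions
#' are deduplicated across models by their formula, so each distinct
#' regression is fitted once. Models are ranked by ascending CICc, ties
#' broken by fewer edges then model id.
#'
#' @param model_set A `model_set` or a (named) list of [causal_dag()]s.
#' @param table Trait table containing every model variable as a column.
#' @param tree A `phylo` object matching the table's species.
#' @param lambda_mode Passed to [fit_pgls()].
#' @return An object of class `ppa_fit`: a ranked data.frame (`$ranking`:
#'   model, edges, claims, C, q, CICc, delta, weight), the per-model fits,
#'   the regression cache, and counters (`$n_regressions`,
#'   `$n_unique_regressions`).
#' @export
fit_model_set <- function(model_set, table, tree, lambda_mode = "fixed1") {
  models <- if (inherits(model_set, "model_set")) model_set$models else model_set
  if (is.null(names(models))) {
    names(models) <- vapply(seq_along(models), function(i) {
      if (!is.null(models[[i]]$id)) models[[i]]$id else paste0("model_", i)
    }, "")
  }
  all_nodes <- unique(unlist(lapply(models, function(m) m$nodes)))
  missing_cols <- setdiff(all_nodes, names(table))
  if (length(missing_cols)) {
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  validate_traits(table, tree)
  table <- standardize_traits(table, all_nodes)
  n <- nrow(table)

  cache <- new.env(parent = emptyenv())
  n_regressions <- 0L
  run_claim <- function(claim) {
    key <- claim$formula
    n_regressions <<- n_regressions + 1L
    if (!is.null(cache[[key]])) return(cache[[key]])
    z <- if (nzchar(claim$conditioning)) {
      strsplit(claim$conditioning, ",", fixed = TRUE)[[1]]
    } else character(0)
    fit <- fit_pgls(table, claim$response, c(z, claim$x), tree,
                    lambda_mode = lambda_mode, standardize = FALSE)
    res <- list(p = unname(fit$p[claim$x]), coef = unname(fit$coefficients[claim$x]))
    cache[[key]] <- res
    res
  }

  fits <- vector("list", length(models))
  names(fits) <- names(models)
  for (nm in names(models)) {
    dag <- models[[nm]]
    claims <- basis_set(dag)
    pvals <- numeric(0)
    if (nrow(claims)) {
      pvals <- vapply(seq_len(nrow(claims)),
                      function(i) run_claim(claims[i, ])$p, 0)
    }
    C <- fisher_c(pmax(pvals, .Machine$double.xmin))
    q <- dag_q(dag)
    fits[[nm]] <- list(dag = dag, claims = claims, p_values = pvals,
                       C = C, q = q, n = n, CICc = cicc(C, q, n))
  }
  ranking <- data.frame(
    model = names(fits),
    edges = vapply(fits, function(f) nrow(f$dag$edges), 0L),
    claims = vapply(fits, function(f) nrow(f$claims), 0L),
    C = vapply(fits, function(f) f$C, 0),
    q = vapply(fits, function(f) f$q, 0),
    CICc = vapply(fits, function(f) f$CICc, 0),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$CICc, ranking$edges, ranking$model), ]
  ranking$delta <- ranking$CICc - min(ranking$CICc)
  w <- exp(-ranking$delta / 2)
  ranking$weight <- w / sum(w)
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, fits = fits, table = table, tree = tree,
                 lambda_mode = lambda_mode,
                 n_regressions = n_regressions,
                 n_unique_regressions = length(ls(cache))),
            class = "ppa_fit")
}

#' @export
print.ppa_fit <- function(x, ...) {
  cat("Phylogenetic path analysis:", nrow(x$ranking), "models,",
      x$n_regressions, "regressions of which",
      x$n_unique_regressions, "unique\n")
  print(head(x$ranking, 10), digits = 4)
  invisible(x)
}

# Path coefficients of one model: each endogenous node regressed on its
# parents; returns data.frame(from, to, coef, se).
path_coefficients <- function(dag, table, tree, lambda_mode = "fixed1") {
  pa <- dag_parents(dag)
  rows <- list()
  for (v in names(pa)) {
    if (!length(pa[[v]])) next
    fit <- fit_pgls(table, v, pa[[v]], tree, lambda_mode = lambda_mode,
                    standardize = FALSE)
    for (p in pa[[v]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        from = p, to = v, coef = unname(fit$coefficients[p]),
        se = unname(fit$se[p]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(0), to = character(0),
                      coef = numeric(0), se = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Full model averaging of path coefficients
#'
#' Averages standardized path coefficients over all models within `cutoff`
#' CICc units of the best, with weights proportional to exp(-delta/2)
#' renormalized over the retained set. Full averaging: a path absent from a
#' model contributes a coefficient (and variance) of zero, shrinking averaged
#' effects toward zero rather than biasing them away from it.
#'
#' @param ppa A `ppa_fit` from [fit_model_set()].
#' @param cutoff CICc window (default 2; the boundary is included).
#' @return An object of class `averaged_model`: data.frame of every ordered
#'   pair appearing in any retained model with averaged `coef` and `se`,
#'   plus the retained model names and weights.
#' @export
average_models <- function(ppa, cutoff = 2) {
  keep <- ppa$ranking[ppa$ranking$delta <= cutoff, ]
  if (!nrow(keep)) stop("no models within the CICc cutoff")
  w <- exp(-keep$delta / 2)
  w <- w / sum(w)
  coefs <- lapply(keep$model, function(nm) {
    path_coefficients(ppa$fits[[nm]]$dag, ppa$table, ppa$tree,
                      lambda_mode = ppa$lambda_mode)
  })
  pairs <- unique(do.call(rbind, lapply(coefs, function(d) d[, c("from", "to")])))
  if (is.null(pairs) || !nrow(pairs)) {
    out <- data.frame(from = character(0), to = character(0),
                      coef = numeric(0), se = numeric(0))
  } else {
    out <- pairs
    out$coef <- 0; out$se <- 0
    for (i in seq_len(nrow(pairs))) {
      b <- 0; v <- 0
      for (m in seq_along(coefs)) {
        d <- coefs[[m]]
        hit <- d$from == pairs$from[i] & d$to == pairs$to[i]
        if (any(hit)) {
          b <- b + w[m] * d$coef[hit][1]
          v <- v + w[m] * d$se[hit][1]^2
        }
        # absent path: contributes zero coefficient and zero variance
      }
      out$coef[i] <- b
      out$se[i] <- sqrt(v)
    }
    rownames(out) <- NULL
  }
  structure(list(coefficients = out, models = keep$model, weights = w),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Full model average over", length(x$models), "models (weights:",
      paste(sprintf("%.3f", x$weights), collapse = ", "), ")\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Export an averaged model as DOT
#'
#' Edge thickness annotation carries the absolute averaged coefficient.
#'
#' @param avg An `averaged_model`.
#' @param path Optional output file.
#' @return DOT text.
#' @export
averaged_to_dot <- function(avg, path = NULL) {
  d <- avg$coefficients
  lines <- c("digraph averaged {",
             if (nrow(d)) sprintf("  %s -> %s [label=\"%.3f\", penwidth=%.2f];",
                                  d$from, d$to, d$coef,
                                  pmax(0.2, 5 * abs(d$coef))),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
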