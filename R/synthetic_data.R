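# Synthetic data with known ground truth: birth-death trees, multi-regime
# Brownian traits, chromosome numbers under a gain/loss/duplication chain,
# and trait tables wired by a known causal DAG. Every downstream stage of
# the pipeline is testable against these generators.

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb outer randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a birth-death tree conditioned on its tip count
#'
#' Complete birth-death tree with `n_tips` surviving tips (extinct lineages
#' pruned), in units of millions of years. Wraps [ape::rphylo()], which
#' simulates conditional on the number of living tips.
#'
#' @param birth Speciation rate (events/Myr), > 0.
#' @param death Extinction rate (events/Myr), >= 0 and < birth.
#' @param n_tips Number of surviving tips (>= 3).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return A `phylo` object with tips `t1..tn`.
#' @export
simulate_tree <- function(birth, death, n_tips, seed = NULL) {
  if (birth <= 0) stop("birth rate must be positive")
  if (death < 0) stop("death rate must be non-negative")
  if (death >= birth) stop("death rate must be below birth rate")
  if (n_tips < 3) stop("need at least 3 tips")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  validate_tree(tree)
  tree
}

# Paint regimes on branches: `shifts` maps node numbers (as names) to regime
# ids; a shift applies to the branch entering the node and everything below
# it, unless overridden by a deeper shift. Unshifted branches belong to the
# root regime (first name of the regime parameter vector/list).
paint_regimes <- function(tree, shifts, root_regime) {
  n_edge <- nrow(tree$edge)
  regime <- rep(root_regime, n_edge)
  if (length(shifts)) {
    shift_nodes <- as.integer(names(shifts))
    # preorder: parents before children (ape edge matrix from reorder)
    tree_pr <- ape::reorder.phylo(tree, "cladewise")
    node_regime <- rep(root_regime, max(tree$edge))
    for (i in seq_len(n_edge)) {
      parent <- tree_pr$edge[i, 1]; child <- tree_pr$edge[i, 2]
      node_regime[child] <- if (child %in% shift_nodes) {
        as.character(shifts[[as.character(child)]])
      } else node_regime[parent]
    }
    # map back to original edge order
    regime <- node_regime[tree$edge[, 2]]
  }
  regime
}

#' Simulate Brownian motion with clade rate regimes
#'
#' Tip values of a Brownian motion whose rate sigma^2 changes at given nodes:
#' each shift applies to the branch entering the node and its whole subtree
#' unless overridden deeper. Tip values are Gaussian with covariance equal to
#' the regime-weighted shared path lengths.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Named numeric vector of per-regime rates
#'   (trait-units^2/Myr); the first element is the root regime.
#' @param shifts Named list/vector mapping node numbers to regime names.
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2, shifts = NULL, root_value = 0,
                        seed = NULL) {
  if (is.null(names(sigma2))) names(sigma2) <- as.character(seq_along(sigma2))
  regime <- paint_regimes(tree, shifts, names(sigma2)[1])
  if (!all(regime %in% names(sigma2))) {
    stop("branch assigned to unknown regime: ",
         paste(setdiff(regime, names(sigma2)), collapse = ", "))
  }
  with_seed(seed, {
    n_node <- max(tree$edge)
    val <- numeric(n_node)
    root <- length(tree$tip.label) + 1L
    val[root] <- root_value
    tree_pr <- ape::reorder.phylo(tree, "cladewise")
    regime_pr <- regime[match(paste(tree_pr$edge[, 1], tree_pr$edge[, 2]),
                              paste(tree$edge[, 1], tree$edge[, 2]))]
    for (i in seq_len(nrow(tree_pr$edge))) {
      parent <- tree_pr$edge[i, 1]; child <- tree_pr$edge[i, 2]
      s2 <- sigma2[[regime_pr[i]]]
      val[child] <- val[parent] +
        rnorm(1, 0, sqrt(s2 * tree_pr$edge.length[i]))
    }
    setNames(val[seq_along(tree$tip.label)], tree$tip.label)
  })
}

#' Simulate a trait table from a known causal DAG
#'
#' Exogenous variables evolve as Brownian motion on the tree; each endogenous
#' variable is the coefficient-weighted sum of its parents plus a
#' phylogenetically correlated (Brownian) residual, scaled so every column
#' has unit variance. Columns are z-scored, so the generating coefficients
#' are standardized path coefficients, recoverable by PGLS.
#'
#' @param tree A `phylo` object.
#' @param dag A [causal_dag()].
#' @param path_coefficients Named numeric vector, names `"from->to"`, values
#'   in [-1, 1]; one entry per edge.
#' @param seed Integer seed.
#' @return Data.frame: `species` plus one column per DAG node.
#' @export
simulate_dag_data <- function(tree, dag, path_coefficients = NULL,
                              seed = NULL) {
  edges <- dag$edges
  if (nrow(edges)) {
    keys <- paste0(edges[, 1], "->", edges[, 2])
    if (is.null(path_coefficients) || !all(keys %in% names(path_coefficients))) {
      stop("path_coefficients must name every edge as 'from->to'; missing: ",
           paste(setdiff(keys, names(path_coefficients)), collapse = ", "))
    }
    if (any(abs(path_coefficients[keys]) > 1)) {
      stop("standardized path coefficients must lie in [-1, 1]")
    }
  }
  ord <- topo_order(dag)
  if (is.null(ord)) stop("dag is cyclic")
  pa <- dag_parents(dag)
  with_seed(seed, {
    cols <- list()
    zscore <- function(v) (v - mean(v)) / sd(v)
    for (v in ord) {
      bm <- simulate_bm(tree, c(base = 1))
      if (!length(pa[[v]])) {
        cols[[v]] <- zscore(bm)
      } else {
        lin <- 0
        for (p in pa[[v]]) {
          lin <- lin + path_coefficients[[paste0(p, "->", v)]] * cols[[p]]
        }
        resid_var <- max(0.05, 1 - var(lin))
        cols[[v]] <- zscore(lin + zscore(bm) * sqrt(resid_var))
      }
    }
    out <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
    for (v in dag$nodes) out[[v]] <- unname(cols[[v]][tree$tip.label])
    out
  })
}

#' Chromosome evolution parameters
#'
#' Container for the gain/loss/duplication rates of the chromosome-number
#' chain: ascending dysploidy rate \eqn{\lambda_0 + \lambda_1 i}, descending
#' \eqn{\delta_0 + \delta_1 i} (clamped at zero), and duplication
#' \eqn{\rho} taking state i to min(2i, max).
#'
#' @param rho Duplication (polyploidy) rate, events/Myr.
#' @param lambda0,delta0 Baseline ascending/descending dysploidy rates,
#'   events/Myr.
#' @param lambda1,delta1 Per-chromosome slopes, events/Myr per chromosome.
#' @return A list of class `chrom_params`.
#' @export
chrom_params <- function(rho = 0, lambda0 = 0, delta0 = 0,
                         lambda1 = 0, delta1 = 0) {
  p <- list(rho = rho, lambda0 = lambda0, delta0 = delta0,
            lambda1 = lambda1, delta1 = delta1)
  if (any(!is.finite(unlist(p)))) stop("parameters must be finite")
  structure(p, class = "chrom_params")
}

#' Simulate chromosome numbers along a tree
#'
#' Exact stochastic simulation (Gillespie) of the gain/loss/duplication chain
#' along every branch. Rates follow the regime painted on each branch;
#' duplications exceeding `n_max` are truncated to `n_max`.
#'
#' @param tree A `phylo` object.
#' @param params A [chrom_params()] or named list of them (one per regime;
#'   first = root regime).
#' @param regime_map Named list/vector mapping node numbers to regime names
#'   (as in [simulate_bm()]); `NULL` for a single regime.
#' @param root_state Haploid number at the root.
#' @param n_max Largest attainable state (default `4 * root_state + 20`).
#' @param seed Integer seed.
#' @return Named integer vector of tip haploid numbers.
#' @export
simulate_chrom <- function(tree, params, regime_map = NULL, root_state,
                           n_max = NULL, seed = NULL) {
  if (inherits(params, "chrom_params")) params <- list(r1 = params)
  if (is.null(n_max)) n_max <- 4 * root_state + 20
  if (root_state < 1 || root_state > n_max) stop("root_state out of bounds")
  regime <- paint_regimes(tree, regime_map, names(params)[1])
  with_seed(seed, {
    n_node <- max(tree$edge)
    state <- integer(n_node)
    root <- length(tree$tip.label) + 1L
    state[root] <- as.integer(root_state)
    tree_pr <- ape::reorder.phylo(tree, "cladewise")
    regime_pr <- regime[match(paste(tree_pr$edge[, 1], tree_pr$edge[, 2]),
                              paste(tree$edge[, 1], tree$edge[, 2]))]
    evolve <- function(i, len, p) {
      t <- 0
      repeat {
        gain <- if (i < n_max) max(0, p$lambda0 + p$lambda1 * i) else 0
        loss <- if (i > 1) max(0, p$delta0 + p$delta1 * i) else 0
        dup <- if (i < n_max) p$rho else 0
        total <- gain + loss + dup
        if (total <= 0) return(i)
        t <- t + rexp(1, total)
        if (t > len) return(i)
        u <- runif(1) * total
        i <- if (u < gain) i + 1L
        else if (u < gain + loss) i - 1L
        else min(2L * i, as.integer(n_max))
      }
    }
    for (k in seq_len(nrow(tree_pr$edge))) {
      parent <- tree_pr$edge[k, 1]; child <- tree_pr$edge[k, 2]
      state[child] <- evolve(state[parent], tree_pr$edge.length[k],
                             params[[regime_pr[k]]])
    }
    setNames(state[seq_along(tree$tip.label)], tree$tip.label)
  })
}

#' Simulate a complete synthetic study dataset
#'
#' One call producing the tree, the causal-DAG trait table, chromosome
#' numbers and tip rate columns under a documented ground truth: a
#' birth-death tree; climate/morphology/diversification columns wired by a
#' known DAG over evolutionary-rate variables; chromosome numbers from the
#' gain/loss/duplication chain. Rate columns (`r_*`) are produced by the DAG
#' like any endogenous variable (diversification-rate estimation is
#' upstream of this package and treated as an input).
#'
#' @param n_tips Number of tips (default 300).
#' @param birth,death Birth-death rates (default 1, 0 /Myr).
#' @param dag Generating DAG over rate variables; default the chain
#'   RB4 -> R2n -> DI with coefficients 0.6.
#' @param path_coefficients Named coefficients for `dag`.
#' @param chrom Chromosome parameters ([chrom_params()]); defaults to the
#'   background dysploidy regime used throughout the package examples.
#' @param root_state Root haploid number (default 15).
#' @param seed Integer seed.
#' @return List with `tree`, `traits` (data.frame including `chrom_n`),
#'   and `config` (echo of all arguments).
#' @export
simulate_dataset <- function(n_tips = 300, birth = 1, death = 0,
                             dag = NULL, path_coefficients = NULL,
                             chrom = chrom_params(rho = 0.007, lambda0 = 2.035,
                                                  delta0 = 1.610, lambda1 = 0.062,
                                                  delta1 = 0.102),
                             root_state = 15, seed = 1) {
  if (is.null(dag)) {
    dag <- causal_dag(c("RB4", "R2n", "RLI", "RCU", "DI"),
                      rbind(c("RB4", "R2n"), c("R2n", "DI")))
    path_coefficients <- c("RB4->R2n" = 0.6, "R2n->DI" = 0.6)
  }
  tree <- simulate_tree(birth, death, n_tips, seed = seed)
  traits <- simulate_dag_data(tree, dag, path_coefficients, seed = seed + 1L)
  traits$chrom_n <- unname(simulate_chrom(tree, chrom, root_state = root_state,
                                          seed = seed + 2L)[traits$species])
  list(tree = tree, traits = traits,
       config = list(n_tips = n_tips, birth = birth, death = death,
                     dag = dag, path_coefficients = path_coefficients,
                     chrom = chrom, root_state = root_state, seed = seed))
}

#' Write a synthetic dataset as plain-text fixtures
#'
#' Emits `tree.nwk`, `traits.csv` and a YAML echo of the configuration.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write.csv(dataset$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  cfg <- dataset$config
  lines <- c(
    paste0("n_tips: ", cfg$n_tips),
    paste0("birth: ", cfg$birth),
    paste0("death: ", cfg$death),
    paste0("root_state: ", cfg$root_state),
    paste0("seed: ", cfg$seed),
    "chrom:",
    paste0("  ", names(unclass(cfg$chrom)), ": ", unlist(cfg$chrom)),
    "path_coefficients:",
    paste0("  ", names(cfg$path_coefficients), ": ", cfg$path_coefficients))
  writeLines(lines, file.path(dir, "config.yaml"))
  invisible(dir)
}
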