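# Closed-form constant-rate birth-death oracle with Gaussian trait-kernel
# bookkeeping: with lambda and mu constant in x, the full likelihood
# factorizes into the birth-death part (Nee et al. closed forms for E(t)
# and the per-lineage density g(t)) and an analytically trackable product
# of Gaussian kernels (all tips share one trait value).
bd_kernel_oracle <- function(tree, lam, mu, s2, tip_sd) {
  r <- lam - mu
  Efun <- function(t) {
    if (mu == 0) return(rep(0, length(t)))
    mu * (1 - exp(-r * t)) / (lam - mu * exp(-r * t))
  }
  gfun <- function(t) (lam - mu)^2 * exp(-r * t) / (lam - mu * exp(-r * t))^2
  depth <- max(ape::node.depth.edgelength(tree))
  age <- depth - ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  po <- ape::reorder.phylo(tree, "postorder")
  logB <- numeric(n_node); v <- numeric(n_node); logc <- numeric(n_node)
  v[1:n_tip] <- tip_sd^2
  done <- logical(n_node)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    contrib <- log(gfun(age[p])) - log(gfun(age[ch]))
    vb <- v[ch] + s2 * po$edge.length[k]
    if (!done[p]) {
      logB[p] <- logB[ch] + contrib; v[p] <- vb; logc[p] <- logc[ch]
      done[p] <- TRUE
    } else {
      logB[p] <- logB[p] + logB[ch] + contrib + log(lam)
      logc[p] <- logc[p] + logc[ch] - 0.5 * log(2 * pi * (v[p] + vb))
      v[p] <- v[p] * vb / (v[p] + vb)
    }
  }
  root <- n_tip + 1
  # D-weighted root integral of the remaining kernel, conditioned on survival
  logB[root] + logc[root] - log(2 * sqrt(pi * v[root])) -
    log(lam * (1 - Efun(depth))^2)
}

quasse_const <- function(lam, mu, s2) {
  quasse_model(list(family = "constant", params = c(c = lam)),
               list(family = "constant", params = c(c = mu)), s2)
}

unit_grid <- function(n) {
  dx <- 1 / n
  list(x = -0.5 + (seq_len(n) - 0.5) * dx, dx = dx, n_bins = n)
}

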