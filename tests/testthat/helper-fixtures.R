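# Small shared fixtures, built in code.

three_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1.5,C:2);")
}

star_tree <- function(n = 10, depth = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(depth, n)
  tr
}

# background dysploidy parameters used across chromosome tests
model1_params <- function() {
  chrom_params(rho = 0.007, lambda0 = 2.035, delta0 = 1.610,
               lambda1 = 0.062, delta1 = 0.102)
}

chain_dag <- function() {
  causal_dag(c("RB4", "R2n", "RLI", "RCU", "DI"),
             rbind(c("RB4", "R2n"), c("R2n", "DI")))
}
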