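#!/usr/bin/env Rscript
# Stage 6: trait-dependent diversification. The chromosome-rate column
# r_chrom is tested as a driver of speciation/extinction by ranking
# constant and non-constant rate functions by AIC. The candidate list is
# kept to the cheap families here; pass --all to fit all sixteen
# family pairs (slow).

library(divpath)

args <- commandArgs(trailingOnly = TRUE)
all_families <- "--all" %in% args
tree <- read_newick("results/data/tree.nwk")
traits <- read_trait_table("results/traits_with_rates.csv")
x <- setNames(traits$r_chrom, traits$species)

if (all_families) {
  lam_f <- c("constant", "linear", "sigmoid", "hump")
  mu_f <- c("constant", "linear", "sigmoid", "hump")
} else {
  lam_f <- c("constant", "sigmoid")
  mu_f <- "constant"
}
fit <- suppressWarnings(
  fit_quasse(tree, x, lambda_families = lam_f, mu_families = mu_f,
             drift = if (all_families) c("bm", "ou") else "bm",
             n_bins = 96, maxit = 120))
print(fit)
write.csv(fit$table, "results/quasse_aic.csv", row.names = FALSE)
cat("Wrote results/quasse_aic.csv\n")
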