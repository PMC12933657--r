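# Enumerated families of causal models relating chromosome, climate and
# morphology variables (means and/or evolutionary rates) to diversification.
#
# All families share one structural grammar of 48 templates:
#   6 base models  = {DI <- chrom, morph <- chrom, both} x {chrom <- bio or not}
#   x 4 expansions = add DI <- morph, DI <- bio, both, or neither
#   x 2            = with or without morph <- bio,
# instantiated with family-specific variable blocks. "morph" and "bio" are
# blocks: an edge into or out of a block applies to every member variable.

template_grid <- function() {
  base <- expand.grid(di_chrom = c(TRUE, FALSE), morph_chrom = c(TRUE, FALSE),
                      chrom_bio = c(TRUE, FALSE), di_morph = c(TRUE, FALSE),
                      di_bio = c(TRUE, FALSE), morph_bio = c(TRUE, FALSE))
  base[base$di_chrom | base$morph_chrom, , drop = FALSE]
}

instantiate_template <- function(t, chrom, bio, morph, di = "DI") {
  e <- list()
  add <- function(from, to) {
    for (f in from) for (g in to) e[[length(e) + 1L]] <<- c(f, g)
  }
  if (t$di_chrom) add(chrom, di)
  if (t$morph_chrom) add(chrom, morph)
  if (t$chrom_bio) add(bio, chrom)
  if (t$di_morph) add(morph, di)
  if (t$di_bio) add(bio, di)
  if (t$morph_bio) add(bio, morph)
  if (!length(e)) return(matrix(character(0), ncol = 2))
  do.call(rbind, e)
}

# Model id: dot-code segments joined by "..": "d.<predictors of DI>",
# "<chrom>.<bio>" when chromosome depends on climate, "<morph>.<pred>" for the
# morphology equation. Tokens per family follow the field's dot-code shorthand
# (r2n / 2n / b2n for rate, mean, or both chromosome variables, etc.).
template_code <- function(t, tok) {
  seg <- character(0)
  if (t$di_chrom || t$di_morph || t$di_bio) {
    p <- c(if (t$di_chrom) tok$chrom, if (t$di_morph) tok$morph,
           if (t$di_bio) tok$bio_di)
    seg <- c(seg, paste(c("d", p), collapse = "."))
  }
  if (t$chrom_bio) seg <- c(seg, paste(c(tok$chrom, tok$bio_chrom), collapse = "."))
  if (t$morph_chrom || t$morph_bio) {
    p <- c(if (t$morph_chrom) tok$chrom, if (t$morph_bio) tok$bio_morph)
    seg <- c(seg, paste(c(tok$morph, p), collapse = "."))
  }
  paste(seg, collapse = "..")
}

# Canonical variable blocks and layouts per enumeration group. The node order
# stored on each DAG is the group's canonical layout (exogenous climate,
# chromosome, morphology, diversification); in the combined family each
# group's layout is padded with the remaining variables of the union. The
# null model lists the chromosome variables first. These layouts orient
# d-separation claims and are part of the package's counting convention.
ms_groups <- function() {
  list(
    rates = list(chrom = "R2n", bio = "RB4", morph = c("RLI", "RCU"),
                 order = c("RB4", "R2n", "RLI", "RCU", "DI"),
                 tok = list(chrom = "r2n", morph = "rmor", bio_di = "rbio",
                            bio_chrom = "rbio", bio_morph = "rbio")),
    means = list(chrom = "C2n", bio = c("B1", "B4", "B7", "B12"),
                 morph = c("LI", "CU"),
                 order = c("B1", "B4", "B7", "B12", "C2n", "LI", "CU", "DI"),
                 tok = list(chrom = "2n", morph = "mor", bio_di = "bio",
                            bio_chrom = "bio", bio_morph = "bio")),
    rates_chromnum = list(chrom = c("C2n", "R2n"), bio = "RB4",
                          morph = c("RLI", "RCU"),
                          order = c("RB4", "C2n", "R2n", "RLI", "RCU", "DI"),
                          tok = list(chrom = "b2n", morph = "rmor", bio_di = "rbio",
                                     bio_chrom = "rbio", bio_morph = "rbio")),
    means_chromrate = list(chrom = c("C2n", "R2n"),
                           bio = c("B1", "B4", "B7", "B12"), morph = c("LI", "CU"),
                           order = c("B1", "B4", "B7", "B12", "R2n", "C2n",
                                     "LI", "CU", "DI"),
                           tok = list(chrom = "b2n", morph = "mor", bio_di = "bio",
                                      bio_chrom = "bio", bio_morph = "bio")),
    means_raterepl = list(chrom = "R2n", bio = c("B1", "B4", "B7", "B12"),
                          morph = c("LI", "CU"),
                          order = c("B1", "B4", "B7", "B12", "R2n", "LI", "CU", "DI"),
                          tok = list(chrom = "r2n", morph = "mor", bio_di = "bio",
                                     bio_chrom = "bio", bio_morph = "bio")),
    rates_numrepl = list(chrom = "C2n", bio = "RB4", morph = c("RLI", "RCU"),
                         order = c("RB4", "C2n", "RLI", "RCU", "DI"),
                         tok = list(chrom = "2n", morph = "rmor", bio_di = "rbio",
                                    bio_chrom = "rbio", bio_morph = "rbio")),
    all_means_rates = list(chrom = c("C2n", "R2n"),
                           bio = c("B1", "B4", "B7", "B12", "RB4"),
                           morph = c("LI", "CU", "RLI", "RCU"),
                           order = c("B1", "B4", "B7", "B12", "RB4", "C2n", "R2n",
                                     "LI", "RLI", "CU", "RCU", "DI"),
                           tok = list(chrom = "b2n", morph = "bmor", bio_di = "bbio",
                                      bio_chrom = "bbio", bio_morph = "bio"))
  )
}

build_group <- function(g, group_name, node_order = g$order) {
  grid <- template_grid()
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    t <- grid[i, ]
    edges <- instantiate_template(t, g$chrom, g$bio, g$morph)
    id <- template_code(t, g$tok)
    models[[i]] <- causal_dag(node_order, edges, id = id)
  }
  names(models) <- vapply(models, function(m) m$id, "")
  attr(models, "group") <- group_name
  models
}

edge_key <- function(dag) {
  if (!nrow(dag$edges)) return("")
  paste(sort(paste(dag$edges[, 1], dag$edges[, 2], sep = ">")), collapse = ";")
}

new_model_set <- function(name, models, groups, nodes) {
  structure(list(name = name, models = models, groups = groups, nodes = nodes),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("model_set '", x$name, "': ", length(x$models), " models over {",
      paste(x$nodes, collapse = ", "), "}\n", sep = "")
  cat("groups:", paste(names(table(x$groups)), table(x$groups),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Candidate models with only evolutionary rates as predictors
#'
#' The 48 causal models over evolutionary rates of temperature seasonality
#' (RB4), chromosome number (R2n), lateral spike unit length (RLI) and culm
#' length (RCU), plus diversification (DI): six chromosome-centred base models,
#' expanded by direct morphological and/or climatic effects on
#' diversification, and doubled by letting morphological rates depend on
#' climatic rates. A no-edge null model is appended for evaluation and
#' regression counting (`include_null = FALSE` drops it).
#'
#' @param include_null Append the null (no-edge) model? Default `TRUE`.
#' @return A `model_set` object; `$models` is a named list of
#'   [causal_dag()]s.
#' @export
build_rate_models <- function(include_null = TRUE) {
  gs <- ms_groups()
  models <- build_group(gs$rates, "rates")
  groups <- rep("rates", length(models))
  if (include_null) {
    models <- c(models, list(null = causal_dag(
      c("R2n", "RB4", "RLI", "RCU", "DI"), NULL, id = "null")))
    groups <- c(groups, "null")
  }
  new_model_set("rates", models, groups, gs$rates$order)
}

#' Candidate models with only species means as predictors
#'
#' The same 48 structural templates instantiated with species means: the four
#' bioclimatic variables (B1, B4, B7, B12) as the climate block, culm (CU)
#' and lateral spike unit length (LI) as the morphology block, and haploid
#' chromosome number (C2n).
#'
#' @inheritParams build_rate_models
#' @return A `model_set` object.
#' @export
build_mean_models <- function(include_null = TRUE) {
  gs <- ms_groups()
  models <- build_group(gs$means, "means")
  groups <- rep("means", length(models))
  if (include_null) {
    models <- c(models, list(null = causal_dag(
      c("C2n", "B1", "B4", "B7", "B12", "LI", "CU", "DI"), NULL, id = "null")))
    groups <- c(groups, "null")
  }
  new_model_set("means", models, groups, gs$means$order)
}

#' Combined candidate models over species means and evolutionary rates
#'
#' Seven instantiations of the 48 structural templates over the union of all
#' twelve variables: the rates-only and means-only families; the rates family
#' augmented with chromosome-number means; the means family augmented with
#' chromosome-number rates; the means family with the chromosome rate
#' substituted for the number; the rates family with the number substituted
#' for the rate; and a family combining every mean with its evolutionary
#' rate. Duplicate graphs arising between families are kept once, in the
#' first family that produces them, leaving 332 distinct models (three full
#' 48s and four 47s). Each model keeps its family's canonical variable
#' layout, padded with the remaining union variables.
#'
#' @inheritParams build_rate_models
#' @return A `model_set` object with 332 models (333 with the null).
#' @export
build_combined_models <- function(include_null = TRUE) {
  gs <- ms_groups()
  seq_names <- c("rates", "means", "rates_chromnum", "means_chromrate",
                 "means_raterepl", "rates_numrepl", "all_means_rates")
  union_nodes <- character(0)
  for (nm in seq_names) union_nodes <- union(union_nodes, gs[[nm]]$order)
  models <- list(); groups <- character(0); seen <- character(0)
  for (nm in seq_names) {
    g <- gs[[nm]]
    layout <- c(g$order, setdiff(union_nodes, g$order))
    grp <- build_group(g, nm, node_order = layout)
    for (m in grp) {
      k <- edge_key(m)
      if (k %in% seen) next
      seen <- c(seen, k)
      mid <- m$id
      if (mid %in% names(models)) mid <- paste(mid, nm, sep = "@")
      models[[mid]] <- m
      groups <- c(groups, nm)
    }
  }
  if (include_null) {
    null_layout <- c("C2n", "R2n", "B1", "B4", "B7", "B12", "RB4",
                     "LI", "CU", "RLI", "RCU", "DI")
    models[["null"]] <- causal_dag(null_layout, NULL, id = "null")
    groups <- c(groups, "null")
  }
  new_model_set("combined", models, groups, union_nodes)
}

#' Count d-separation regressions implied by a model set
#'
#' `total` sums basis-set sizes over all models (the number of phylogenetic
#' regressions a path analysis of the set performs, duplicates included);
#' `unique` counts distinct regressions after deduplication by the full
#' regression formula (response, ordered conditioning set, tested predictor).
#'
#' @param model_set A `model_set` from one of the builders, or a plain list
#'   of [causal_dag()]s.
#' @return A list with elements `total` and `unique`.
#' @export
count_regressions <- function(model_set) {
  models <- if (inherits(model_set, "model_set")) model_set$models else model_set
  formulas <- unlist(lapply(models, function(m) basis_set(m)$formula))
  list(total = length(formulas), unique = length(unique(formulas)))
}
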