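# End-to-end orchestration: synthesize or load data, compute tip rates
# (chromosome and traits), build and fit the path-analysis model families,
# average the best models, and fit the trait-dependent diversification
# models — under one configuration with a fixed seed.

#' Pipeline configuration
#'
#' Validates and freezes the options of a full analysis run.
#'
#' @param tree_file,traits_file Input paths (Newick, CSV); `NULL` to
#'   simulate instead.
#' @param sim Arguments for [simulate_dataset()] when simulating (list).
#' @param families Model families to fit: subset of
#'   `c("rates", "means", "combined")`.
#' @param cutoff CICc model-averaging window (default 2).
#' @param lambda_mode PGLS residual mode, see [fit_pgls()].
#' @param chrom_shifts Run the chromosome shift search? Default `TRUE`.
#' @param min_clade,max_regimes Chromosome shift-search settings (10, 40).
#' @param trait_columns Columns to compute evolutionary rates for.
#' @param quasse_column Trait column for the diversification analysis
#'   (default `r_chrom`); `NULL` to skip.
#' @param quasse_bins Grid size for the diversification likelihood.
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree_file = NULL, traits_file = NULL, sim = list(),
                            families = c("rates"), cutoff = 2,
                            lambda_mode = "fixed1", chrom_shifts = TRUE,
                            min_clade = 10, max_regimes = 40,
                            trait_columns = c("BIO4", "culm", "spike"),
                            quasse_column = "r_chrom", quasse_bins = 128,
                            seed = 1, out_dir = tempfile("divpath_run")) {
  stopifnot(all(families %in% c("rates", "means", "combined")))
  if (!is.null(tree_file) && !file.exists(tree_file)) {
    stop("tree_file not found: ", tree_file)
  }
  if (!is.null(traits_file) && !file.exists(traits_file)) {
    stop("traits_file not found: ", traits_file)
  }
  structure(list(tree_file = tree_file, traits_file = traits_file, sim = sim,
                 families = families, cutoff = cutoff,
                 lambda_mode = lambda_mode, chrom_shifts = chrom_shifts,
                 min_clade = min_clade, max_regimes = max_regimes,
                 trait_columns = trait_columns, quasse_column = quasse_column,
                 quasse_bins = quasse_bins, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

write_stage_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: data (simulate or load + validate);
#' chromosome model and per-tip dysploidy rates (`r_chrom`); trait rate
#' regimes (`r_<col>` columns); path analyses per requested family with
#' CICc ranking and full model averaging; trait-dependent diversification
#' fits. Every stage writes its tables under the configured output
#' directory; the returned manifest lists stages, artifact paths with
#' checksums, and timings.
#'
#' @param config A [pipeline_config()].
#' @return A manifest list (also written as `manifest.json` when the
#'   jsonlite package is available).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  t_all <- Sys.time()
  stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- fn()
    manifest$stages[[name]] <<- c(
      list(elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3)),
      out)
    invisible(out)
  }

  # --- data ---
  env <- new.env()
  stage("data", function() {
    if (!is.null(config$tree_file)) {
      env$tree <- read_newick(config$tree_file)
      env$traits <- read_trait_table(config$traits_file)
      validate_traits(env$traits, env$tree)
      list(source = "files", n_tips = length(env$tree$tip.label))
    } else {
      ds <- do.call(simulate_dataset,
                    c(config$sim, list(seed = config$seed)))
      env$tree <- ds$tree
      env$traits <- ds$traits
      write_fixture(ds, file.path(config$out_dir, "data"))
      list(source = "simulated", n_tips = length(env$tree$tip.label))
    }
  })

  # --- chromosome rates ---
  stage("chrom", function() {
    chrom_n <- setNames(env$traits$chrom_n, env$traits$species)
    fit <- fit_chrom_model(env$tree, chrom_n,
                           allow_shifts = config$chrom_shifts,
                           min_clade = config$min_clade,
                           max_regimes = config$max_regimes)
    env$chrom_fit <- fit
    env$traits$r_chrom <- unname(tip_dysploidy_rate(fit)[env$traits$species])
    reg <- do.call(rbind, lapply(names(fit$regimes), function(nm) {
      p <- fit$regimes[[nm]]
      data.frame(regime = nm, rho = p$rho, lambda0 = p$lambda0,
                 delta0 = p$delta0, lambda1 = p$lambda1, delta1 = p$delta1)
    }))
    path <- write_stage_table(reg, config$out_dir, "chrom_regimes")
    list(n_regimes = length(fit$regimes), AIC = fit$AIC,
         artifact = path, checksum = unname(tools::md5sum(path)))
  })

  # --- trait rates ---
  stage("trait_rates", function() {
    cols <- intersect(config$trait_columns, names(env$traits))
    if (length(cols)) {
      env$traits <- add_tip_rates(env$traits, env$tree, cols)
    }
    path <- write_stage_table(env$traits, config$out_dir, "traits_with_rates")
    list(columns = cols, artifact = path,
         checksum = unname(tools::md5sum(path)))
  })

  # --- path analyses ---
  stage("ppa", function() {
    out <- list()
    for (fam in config$families) {
      ms <- switch(fam, rates = build_rate_models(),
                   means = build_mean_models(),
                   combined = build_combined_models())
      cols <- setdiff(unique(unlist(lapply(ms$models, function(m) m$nodes))),
                      names(env$traits))
      if (length(cols)) {
        stop("ppa stage: trait table lacks columns for family '", fam,
             "': ", paste(cols, collapse = ", "))
      }
      fit <- fit_model_set(ms, env$traits, env$tree,
                           lambda_mode = config$lambda_mode)
      avg <- average_models(fit, cutoff = config$cutoff)
      p1 <- write_stage_table(fit$ranking, config$out_dir,
                              paste0("ppa_", fam, "_ranking"))
      p2 <- write_stage_table(avg$coefficients, config$out_dir,
                              paste0("ppa_", fam, "_averaged"))
      averaged_to_dot(avg, file.path(config$out_dir,
                                     paste0("ppa_", fam, "_averaged.dot")))
      out[[fam]] <- list(
        best = fit$ranking$model[1],
        n_regressions = fit$n_regressions,
        n_unique = fit$n_unique_regressions,
        artifacts = c(p1, p2),
        checksums = unname(tools::md5sum(c(p1, p2))))
    }
    out
  })

  # --- trait-dependent diversification ---
  stage("quasse", function() {
    col <- config$quasse_column
    if (is.null(col)) return(list(skipped = TRUE))
    if (!col %in% names(env$traits)) {
      stop("quasse stage: column '", col, "' not present in the trait table")
    }
    x <- setNames(env$traits[[col]], env$traits$species)
    fit <- suppressWarnings(
      fit_quasse(env$tree, x, lambda_families = c("constant", "sigmoid"),
                 mu_families = "constant", n_bins = config$quasse_bins))
    path <- write_stage_table(fit$table, config$out_dir, "quasse_aic")
    list(best = fit$table$model[1], artifact = path,
         checksum = unname(tools::md5sum(path)))
  })

  manifest$elapsed_s <- round(as.numeric(Sys.time() - t_all, units = "secs"), 3)
  manifest$r_version <- as.character(getRversion())
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  manifest
}
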