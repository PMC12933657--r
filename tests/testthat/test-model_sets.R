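test_that("rates family has the documented block structure", {
  ms <- build_rate_models()
  hyp <- ms$models[names(ms$models) != "null"]
  expect_length(hyp, 48)
  expect_true(all(vapply(hyp, function(m)
    setequal(m$nodes, c("RB4", "R2n", "RLI", "RCU", "DI")), TRUE)))
  # all acyclic by construction (causal_dag validates); distinct edge sets
  keys <- vapply(hyp, divpath:::edge_key, "")
  expect_false(anyDuplicated(keys) > 0)
  # the chain model carries exactly its two edges and no morphology edges
  m <- ms$models[["d.r2n..r2n.rbio"]]
  expect_equal(nrow(m$edges), 2)
  expect_setequal(paste(m$edges[, 1], m$edges[, 2]),
                  c("R2n DI", "RB4 R2n"))
})

test_that("means family instantiates climate and morphology blocks", {
  ms <- build_mean_models()
  hyp <- ms$models[names(ms$models) != "null"]
  expect_length(hyp, 48)
  best <- ms$models[["d.2n..2n.bio..mor.bio"]]
  ed <- paste(best$edges[, 1], best$edges[, 2])
  expect_true("C2n DI" %in% ed)
  expect_true(all(paste(c("B1", "B4", "B7", "B12"), "C2n") %in% ed))
  expect_true(all(c("B1 LI", "B12 CU") %in% ed))
  # exogenous climate nodes have in-degree 0 everywhere
  for (m in hyp) {
    expect_false(any(m$edges[, 2] %in% c("B1", "B4", "B7", "B12")))
  }
})

test_that("combined family has 332 distinct models in the documented groups", {
  ms <- build_combined_models()
  hyp <- ms$models[names(ms$models) != "null"]
  expect_length(hyp, 332)
  keys <- vapply(hyp, divpath:::edge_key, "")
  expect_false(anyDuplicated(keys) > 0)
  grp <- table(ms$groups[ms$groups != "null"])
  expect_equal(unname(grp["means_chromrate"]), 47L)
  expect_equal(unname(grp["rates"]), 48L)
  expect_equal(unname(grp["means"]), 48L)
  # the best combined model predicts DI from both chromosome variables
  best <- ms$models[["d.b2n..b2n.bbio..bmor.bio"]]
  ed <- paste(best$edges[, 1], best$edges[, 2])
  expect_true(all(c("C2n DI", "R2n DI") %in% ed))
})

test_that("regression counts are stable and unique <= total", {
  for (build in list(build_rate_models, build_mean_models)) {
    ms <- build()
    ct <- count_regressions(ms)
    expect_lte(ct$unique, ct$total)
    shuffled <- ms
    shuffled$models <- ms$models[rev(seq_along(ms$models))]
    expect_equal(count_regressions(shuffled)$total, ct$total)
    expect_equal(count_regressions(shuffled)$unique, ct$unique)
  }
})
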