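test_that("configuration validates its distribution parameters", {
  cfg <- simulation_config()
  expect_equal(cfg$n_varieties, 14L)
  expect_equal(cfg$n_replicates, 3L)
  expect_equal(cfg$nd_fraction_mean, 0.443)
  expect_equal(cfg$nd_fraction_sd, 0.129)
  expect_error(simulation_config(element_gsd = 0.9), "gsd")
  expect_error(simulation_config(nd_fraction_mean = 1.2), "0, 1")
  expect_error(simulation_config(nd_fraction_sd = 0.6), "beta")
  expect_error(simulation_config(
    composition_means = c(moisture = 60, carbohydrates = 60)), "100")
})

test_that("the default design yields 84 analyzable records", {
  study <- generate_study(seed = 10)
  analyzable <- study$samples |>
    dplyr::filter(.data$preparation %in% c("cooked", "digestible")) |>
    dplyr::distinct(.data$variety, .data$preparation, .data$replicate)
  expect_equal(nrow(analyzable), 84)
  expect_equal(nrow(study$splits), 14)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_study(simulation_config(n_varieties = 5), seed = 99)
  b <- generate_study(simulation_config(n_varieties = 5), seed = 99)
  expect_identical(a, b)
  c_ <- generate_study(simulation_config(n_varieties = 5), seed = 100)
  expect_false(identical(a$samples$value, c_$samples$value))
})

test_that("digestible and non-digestible recombine exactly to cooked", {
  study <- generate_study(simulation_config(n_varieties = 6), seed = 4)
  wide <- tidyr::pivot_wider(study$samples, names_from = "preparation",
                             values_from = "value")
  expect_equal(wide$digestible + wide$non_digestible, wide$cooked)
  expect_true(all(wide$digestible >= 0 & wide$non_digestible >= 0))
  expect_equal(study$splits$non_digestible_pct +
                 study$splits$digestible_pct, rep(100, 6))
})

test_that("degenerate noise collapses replicates onto the variety mean", {
  cfg <- simulation_config(n_varieties = 3, element_gsd = 1,
                           replicate_cv = 0, nd_fraction_sd = 0,
                           composition_cv = 0)
  study <- generate_study(cfg, seed = 1)
  cooked <- study$samples[study$samples$preparation == "cooked", ]
  by_el <- split(cooked$value, cooked$element)
  for (e in names(by_el)) {
    expect_equal(by_el[[e]], rep(cfg$element_gm[[e]], 9))
  }
  rec <- recover_parameters(study)
  expect_equal(rec$nd_fraction$estimate, 0.443)   # exact recovery
  expect_equal(stats::setNames(rec$element_gm$estimate,
                               rec$element_gm$element)[names(cfg$element_gm)],
               cfg$element_gm)
})

test_that("pipeline closure: generated studies run end to end", {
  study <- generate_study(simulation_config(n_varieties = 5), seed = 12)
  res <- run_full_analysis(study$samples)
  expect_named(res, c("concentration_summary", "bioaccessibility",
                      "risk_per_element", "risk_per_variety"))
  expect_true(all(res$risk_per_variety$tthq <= 1))
  # measured bioaccessibility reproduces the generator's ground truth
  truth_b <- study$truth$bioaccessibility
  bio <- res$bioaccessibility
  got <- 100 * truth_b[cbind(bio$variety, bio$element)]
  expect_equal(bio$pct, unname(got), tolerance = 1e-9)
})

test_that("moment estimates recover the generating parameters", {
  cfg <- simulation_config(n_varieties = 60, n_replicates = 5)
  study <- generate_study(cfg, seed = 2024)
  rec <- recover_parameters(study)
  # each estimate within 3 standard errors of its generating value
  expect_lt(abs(rec$nd_fraction$estimate - cfg$nd_fraction_mean),
            3 * rec$nd_fraction$se)
  for (i in seq_len(nrow(rec$bioaccessibility))) {
    e <- rec$bioaccessibility$element[i]
    expect_lt(abs(rec$bioaccessibility$estimate[i] -
                    cfg$bioaccessibility_mean[[e]]),
              3 * rec$bioaccessibility$se[i])
  }
})
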