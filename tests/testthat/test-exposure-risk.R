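test_that("estimated daily intake matches hand arithmetic", {
  expect_equal(edi(1e-3), 7.67e-3 / 68.5)                 # 1.1197e-4
  expect_equal(edi(1e-3), 1.1197e-4, tolerance = 1e-4)
  expect_equal(edi(1e-3, carcinogenic = TRUE),
               7.67e-3 / 68.5 * 54 / 70)
  expect_equal(edi(0), 0)
  expect_error(edi(-1), "non-negative")
})

test_that("carcinogenic and non-carcinogenic intakes differ by ED/70y", {
  m <- exposure_model()
  mcs <- 10^runif(20, -9, -2)
  expect_equal(edi(mcs, m, carcinogenic = TRUE) / edi(mcs, m),
               rep(54 / 70, 20))
})

test_that("risk quotients are linear in concentration", {
  m <- exposure_model()
  mc <- c(1e-6, 2e-6, 5e-5)
  for (k in c(2, 10)) {
    expect_equal(edi(k * mc, m), k * edi(mc, m))
    expect_equal(thq(edi(k * mc, m), 4e-4), k * thq(edi(mc, m), 4e-4))
    expect_equal(as.numeric(ilcr(edi(k * mc, m, TRUE), 1.5)),
                 k * as.numeric(ilcr(edi(mc, m, TRUE), 1.5)))
  }
})

test_that("hazard quotient divides intake by the reference dose", {
  expect_equal(thq(4e-4, 4e-4), 1)
  expect_equal(thq(1.1197e-4, 0.0004), 0.2799, tolerance = 1e-3)
  expect_equal(thq(0, 0.003), 0)
  expect_error(thq(1e-4, NA_real_), "rfd")
  expect_error(thq(1e-4, 0), "rfd")
})

test_that("total hazard quotient sums elements and classifies at 1", {
  z <- tthq(c(Al = 0, Cr = 0, As = 0, Cd = 0, Pb = 0))
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "classification"), "acceptable")
  expect_equal(as.numeric(tthq(rep(0.001, 5))), 0.005)
  # oracle: brute-force sum over an independently enumerated element set
  set.seed(11)
  vals <- stats::setNames(runif(5, 0, 0.3), c("Al", "Cr", "As", "Cd", "Pb"))
  brute <- 0
  for (e in c("Pb", "Cd", "As", "Cr", "Al")) brute <- brute + vals[[e]]
  expect_equal(as.numeric(tthq(vals)), brute)
  # boundary: exactly 1 is still acceptable; any excess is not
  expect_equal(attr(tthq(c(0.5, 0.5)), "classification"), "acceptable")
  expect_equal(attr(tthq(c(0.5, 0.7)), "classification"),
               "unacceptable_noncarc")
  expect_equal(attr(tthq(c(a = 1.2)), "classification"),
               "unacceptable_noncarc")
})

test_that("cancer risk multiplies by the slope factor and classifies at 1e-4", {
  r <- ilcr(8.638e-5, 1.5)
  expect_equal(as.numeric(r), 1.296e-4, tolerance = 1e-3)
  expect_equal(attr(r, "classification"), "intolerable_carc")
  expect_equal(as.numeric(ilcr(1e-8, 0.0085)), 8.5e-11)
  expect_equal(as.numeric(ilcr(0, 0.38)), 0)
  expect_equal(attr(ilcr(1e-4 / 1.5, 1.5), "classification"),
               "tolerable_carc")  # boundary inclusive
  expect_true(is.na(as.numeric(ilcr(1e-5, NA_real_))))  # no CSF: no ILCR
})

test_that("percent of reference follows the intake chain", {
  expect_equal(pct_of_reference(3, 3), 100)
  expect_equal(pct_of_reference(0, 0.5), 0)
  expect_equal(pct_of_reference(1.786e-3 * 7.67, 0.0004 * 68.5), 50,
               tolerance = 1e-3)
  expect_error(pct_of_reference(1, 0), "positive")
})

test_that("worst-case LOQ substitution replaces censored values", {
  params <- element_params()
  params$loq <- c(NA, 1e-5, 1e-5, 1e-5, 1e-5)  # Al has none
  params$loq_unit <- "ug/g"
  s <- tibble::tibble(
    variety = "A", preparation = "cooked", replicate = 1:3,
    element = "As", value = c(5e-6, 2e-5, NA), unit = "ug/g"
  )
  out <- loq_substitute(s, params)
  expect_equal(out$value, c(1e-5, 2e-5, 1e-5))
  expect_equal(out$loq_substituted, c(TRUE, FALSE, TRUE))
  # respects the sample's unit when comparing
  s_ng <- s
  s_ng$value <- s$value * 1000
  s_ng$unit <- "ng/g"
  out_ng <- loq_substitute(s_ng, params)
  expect_equal(out_ng$value, c(1e-2, 2e-2, 1e-2))
  # censored value for an element without a registered LOQ is an error
  s_al <- s
  s_al$element <- "Al"
  expect_error(loq_substitute(s_al, params, elements = "Al"), "Al")
})

test_that("assessment aggregates per-element risk into variety totals", {
  s <- tiny_samples()
  res <- assess_risk(s, preparation = "digestible")
  expect_s3_class(res, "risk_assessment")
  expect_equal(nrow(res$per_element), 4)
  expect_equal(nrow(res$per_variety), 2)
  # TTHQ is the exact sum of the element THQs
  for (v in c("A", "B")) {
    expect_equal(res$per_variety$tthq[res$per_variety$variety == v],
                 sum(res$per_element$thq[res$per_element$variety == v]))
  }
  # Al carries no ILCR; totals only sum the elements that have one
  al <- res$per_element$ilcr[res$per_element$element == "Al"]
  expect_true(all(is.na(al)))
  expect_error(assess_risk(s, preparation = "raw"), "raw")
  s_bad <- s
  s_bad$element[which(s_bad$preparation == "digestible")[1]] <- "Hg"
  expect_error(assess_risk(s_bad), "Hg")
})
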