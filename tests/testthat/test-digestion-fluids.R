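test_that("stock dilution arithmetic matches the recipe sheet", {
  expect_equal(stock_to_fluid(2, 11.8), 47.2)    # gastric NaCl
  expect_equal(stock_to_fluid(1, 42.5), 85)      # intestinal NaHCO3
  expect_equal(stock_to_fluid(6, 1.3), 15.6)     # gastric HCl
  expect_equal(stock_to_fluid(6, 0.7), 8.4)      # intestinal HCl
  expect_equal(stock_to_fluid(2, 9.6), 38.4)     # intestinal NaCl
  expect_equal(stock_to_fluid(0.5, 0), 0)
  expect_error(stock_to_fluid(2, -1), "non-negative")
  expect_error(stock_to_fluid(2, 1, 0), "positive")
})

test_that("stock dilution is linear in the dispensed volume", {
  vols <- c(0.06, 0.5, 6.8, 15.1, 42.5)
  expect_equal(stock_to_fluid(0.5, 2 * vols), 2 * stock_to_fluid(0.5, vols))
})

test_that("mixing halves every constituent concentration", {
  expect_equal(fluid_to_final_mixture(1.5), 0.75)    # salivary CaCl2
  expect_equal(fluid_to_final_mixture(0.15), 0.075)  # gastric CaCl2
  expect_equal(fluid_to_final_mixture(3.3, 1.0), 3.3)
  expect_error(fluid_to_final_mixture(1, 0), "0, 1")
  expect_error(fluid_to_final_mixture(1, 1.5), "0, 1")
})

test_that("enzyme dosing converts activity to solid mass", {
  expect_equal(enzyme_mass(2000, 367, 10), 54.50, tolerance = 1e-3)
  expect_equal(enzyme_mass(75, 75, 1), 1)
  expect_equal(enzyme_mass(0, 367, 10), 0)
  expect_error(enzyme_mass(2000, 0, 10), "positive")
})

test_that("full recipes reproduce the printed fluid concentrations", {
  # printed cells (mmol/L) at their printed decimal precision
  printed <- list(
    SSF = c(KCl = 15.1, KH2PO4 = 3.7, NaHCO3 = 13.6, "MgCl2(H2O)6" = 0.15,
            "(NH4)2CO3" = 0.06, HCl = 1.1, "CaCl2(H2O)2" = 1.5),
    SGF = c(KCl = 6.9, KH2PO4 = 0.9, NaHCO3 = 25, NaCl = 47.2,
            "MgCl2(H2O)6" = 0.1, "(NH4)2CO3" = 0.5, HCl = 15.6,
            "CaCl2(H2O)2" = 0.15),
    SIF = c(KCl = 6.8, KH2PO4 = 0.8, NaHCO3 = 85, NaCl = 38.4,
            "MgCl2(H2O)6" = 0.33, HCl = 8.4, "CaCl2(H2O)2" = 0.6)
  )
  decimals <- function(x) {
    s <- sub("0+$", "", sub(".*\\.", "", format(x, scientific = FALSE)))
    ifelse(grepl("\\.", format(x, scientific = FALSE)), nchar(s), 0)
  }
  for (fluid in names(printed)) {
    rec <- full_recipe(fluid)
    for (const in names(printed[[fluid]])) {
      got <- rec$fluid_mM[rec$constituent == const]
      want <- printed[[fluid]][[const]]
      expect_equal(round(got, decimals(want)), want,
                   info = paste(fluid, const))
    }
    # constituents absent from the fluid never appear with a dose
    expect_false(any(rec$fluid_mM[!rec$constituent %in%
                                    c(names(printed[[fluid]]), "NaOH")] > 0))
  }
  # the named headline cells are exact, not just printed-precision
  expect_equal(full_recipe("SGF")$fluid_mM[full_recipe("SGF")$constituent == "NaCl"], 47.2)
  expect_equal(full_recipe("SIF")$fluid_mM[full_recipe("SIF")$constituent == "NaHCO3"], 85)
  expect_error(full_recipe("SXF"))
})

test_that("amount of substance is conserved from stock to final mixture", {
  reg <- fluid_stock_registry()
  for (fluid in c("SSF", "SGF", "SIF")) {
    rec <- full_recipe(fluid, fluid_mL = 500, mix_dilution = 0.5)
    has_stock <- !is.na(rec$stock_mol_per_L) & rec$volume_mL > 0
    mmol_stock <- rec$stock_mol_per_L[has_stock] * rec$volume_mL[has_stock]
    mmol_fluid <- rec$fluid_mM[has_stock] * 500 / 1000
    mmol_mix <- rec$final_mixture_mM[has_stock] * (500 / 0.5) / 1000
    expect_equal(mmol_fluid, mmol_stock)
    expect_equal(mmol_mix, mmol_stock)
  }
})

test_that("fluid pH targets are salivary 7, gastric 3, intestinal 7", {
  expect_equal(fluid_ph("SSF"), 7)
  expect_equal(fluid_ph("SGF"), 3)
  expect_equal(fluid_ph("SIF"), 7)
})
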