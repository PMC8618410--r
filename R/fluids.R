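# Simulated digestion fluid recipes (INFOGEST harmonized static
# protocol): electrolyte stock solutions are combined to 500 mL of
# simulated salivary (SSF), gastric (SGF), or intestinal (SIF) fluid,
# which is then mixed 50:50 with food/chyme, halving every constituent
# concentration in the final digestion mixture.

#' Electrolyte stock registry for the simulated digestion fluids
#'
#' Stock solution concentrations and the volumes dispensed into 500 mL
#' of each simulated fluid.  `NA` volumes mean the constituent is not
#' part of that fluid (or, for NaOH, is reserved for pH adjustment and
#' dosed as needed).  CaCl2 is added at mixing time rather than to the
#' electrolyte stock, so the registry stores its target concentration in
#' each fluid directly (`cacl2_mM`).
#'
#' The HCl stock is stored as 6 mol/L: that molarity is the only reading
#' under which the dispensed volumes give the recipe's gastric and
#' intestinal acid concentrations (15.6 and 8.4 mmol/L).
#'
#' @return A tibble with columns `constituent`, `stock_g_per_L`,
#'   `stock_mol_per_L`, `ssf_mL`, `sgf_mL`, `sif_mL`, `ssf_mM`,
#'   `sgf_mM`, `sif_mM` (the `*_mM` columns only for CaCl2, which has no
#'   stock volume).
#' @export
#' @examples
#' fluid_stock_registry()
fluid_stock_registry <- function() {
  tibble::tribble(
    ~constituent, ~stock_g_per_L, ~stock_mol_per_L, ~ssf_mL, ~sgf_mL, ~sif_mL,
    "KCl", 37.3, 0.5, 15.1, 6.9, 6.8,
    "KH2PO4", 68, 0.5, 3.7, 0.9, 0.8,
    "NaHCO3", 84, 1, 6.8, 12.5, 42.5,
    "NaCl", 117, 2, NA, 11.8, 9.6,
    "MgCl2(H2O)6", 30.5, 0.15, 0.5, 0.4, 1.1,
    "(NH4)2CO3", 48, 0.5, 0.06, 0.5, NA,
    "NaOH", 1, NA, NA, NA, NA,
    "HCl", 6, 6, 0.09, 1.3, 0.7,
    "CaCl2(H2O)2", 44.1, 0.3, NA, NA, NA
  ) |>
    dplyr::mutate(
      ssf_mM = ifelse(.data$constituent == "CaCl2(H2O)2", 1.5, NA),
      sgf_mM = ifelse(.data$constituent == "CaCl2(H2O)2", 0.15, NA),
      sif_mM = ifelse(.data$constituent == "CaCl2(H2O)2", 0.6, NA)
    )
}

#' Concentration of a stock aliquot in a simulated fluid
#'
#' Dilution of `stock_mL` of a `stock_mol_per_L` stock into
#' `fluid_mL` of fluid, in mmol/L.
#'
#' @param stock_mol_per_L Stock concentration, mol/L.
#' @param stock_mL Dispensed stock volume, mL.
#' @param fluid_mL Final fluid volume, mL (500 in the standard recipe).
#' @return Concentration in the fluid, mmol/L.
#' @export
#' @examples
#' stock_to_fluid(2, 11.8)   # NaCl in SGF: 47.2 mmol/L
stock_to_fluid <- function(stock_mol_per_L, stock_mL, fluid_mL = 500) {
  stopifnot(is.numeric(stock_mol_per_L), is.numeric(stock_mL),
            is.numeric(fluid_mL))
  if (any(stock_mL < 0, na.rm = TRUE) ||
      any(stock_mol_per_L < 0, na.rm = TRUE)) {
    stop("stock volumes and concentrations must be non-negative",
         call. = FALSE)
  }
  if (any(fluid_mL <= 0)) stop("fluid volume must be positive", call. = FALSE)
  # mol/L * mL / mL * 1000 -> mmol/L
  stock_mol_per_L * stock_mL / fluid_mL * 1000
}

#' Dilution into the final digestion mixture
#'
#' The simulated fluid is mixed with food (oral phase) or with the bolus
#' or chyme of the previous phase at a final 50:50 ratio, so every
#' constituent concentration is multiplied by the mixing dilution
#' (default 0.5).
#'
#' @param fluid_mM Concentration in the simulated fluid, mmol/L (any
#'   concentration-like quantity works: the operation is a pure scaling).
#' @param mix_dilution Dilution factor in (0, 1].
#' @return Concentration in the final digestion mixture.
#' @export
#' @examples
#' fluid_to_final_mixture(1.5)   # salivary-phase CaCl2: 0.75 mM
fluid_to_final_mixture <- function(fluid_mM, mix_dilution = 0.5) {
  stopifnot(is.numeric(fluid_mM), is.numeric(mix_dilution))
  if (any(mix_dilution <= 0 | mix_dilution > 1)) {
    stop("mix_dilution must lie in (0, 1]", call. = FALSE)
  }
  fluid_mM * mix_dilution
}

#' Enzyme solid mass needed for a target activity
#'
#' Mass of enzyme preparation (mg of solid) required to reach
#' `target_activity` (U/mL) in `mixture_mL` of digestion mixture, given
#' the preparation's specific activity (U/mg solid), e.g. porcine pepsin
#' at 367 U/mg dosed to 2000 U/mL in the gastric phase.
#'
#' @param target_activity Target activity in the mixture, U/mL.
#' @param specific_activity Specific activity of the solid, U/mg.
#' @param mixture_mL Volume of the digestion mixture, mL.
#' @return Required mass of solid, mg.
#' @export
#' @examples
#' enzyme_mass(2000, 367, 10)
enzyme_mass <- function(target_activity, specific_activity, mixture_mL) {
  stopifnot(is.numeric(target_activity), is.numeric(specific_activity),
            is.numeric(mixture_mL))
  if (any(target_activity < 0) || any(mixture_mL < 0)) {
    stop("activities and volumes must be non-negative", call. = FALSE)
  }
  if (any(specific_activity <= 0)) {
    stop("specific activity must be positive", call. = FALSE)
  }
  target_activity * mixture_mL / specific_activity
}

#' Full recipe sheet for a simulated digestion fluid
#'
#' Computes, for every constituent of the requested fluid, its
#' concentration in the fluid from the stock registry and its
#' concentration in the final 50:50 digestion mixture.  CaCl2 (dosed at
#' mixing) and pH-adjustment NaOH (volume on demand) are carried with
#' their registry conventions.
#'
#' @param fluid `"SSF"`, `"SGF"`, or `"SIF"`.
#' @param fluid_mL Fluid batch volume, mL.
#' @param mix_dilution Dilution into the final mixture.
#' @param registry Stock registry, by default [fluid_stock_registry()].
#' @return A tibble with columns `constituent`, `stock_mol_per_L`,
#'   `volume_mL`, `fluid_mM`, `final_mixture_mM`; rows with no role in
#'   the fluid are dropped.
#' @export
#' @examples
#' full_recipe("SGF")
full_recipe <- function(fluid = c("SSF", "SGF", "SIF"), fluid_mL = 500,
                        mix_dilution = 0.5,
                        registry = fluid_stock_registry()) {
  fluid <- match.arg(toupper(fluid), c("SSF", "SGF", "SIF"))
  vol_col <- paste0(tolower(fluid), "_mL")
  mM_col <- paste0(tolower(fluid), "_mM")
  vol <- registry[[vol_col]]
  direct <- registry[[mM_col]]
  fluid_mM <- ifelse(
    !is.na(direct), direct,
    stock_to_fluid(registry$stock_mol_per_L, ifelse(is.na(vol), 0, vol),
                   fluid_mL)
  )
  out <- tibble::tibble(
    constituent = registry$constituent,
    stock_mol_per_L = registry$stock_mol_per_L,
    volume_mL = vol,
    fluid_mM = fluid_mM,
    final_mixture_mM = fluid_to_final_mixture(fluid_mM, mix_dilution)
  )
  # keep constituents that are part of this fluid (a dispensed volume or
  # a direct target concentration); NaOH is retained as the optional
  # pH-adjustment row with zero dose
  keep <- !is.na(out$volume_mL) | !is.na(direct) |
    registry$constituent == "NaOH"
  out <- out[keep, ]
  out$volume_mL[is.na(out$volume_mL)] <- 0
  out$fluid_mM[out$constituent == "NaOH"] <- 0
  out$final_mixture_mM[out$constituent == "NaOH"] <- 0
  out
}

#' Target pH of each simulated fluid
#'
#' @param fluid `"SSF"`, `"SGF"`, or `"SIF"`.
#' @return The target pH (7, 3, and 7 respectively).
#' @export
fluid_ph <- function(fluid = c("SSF", "SGF", "SIF")) {
  fluid <- match.arg(toupper(fluid), c("SSF", "SGF", "SIF"))
  c(SSF = 7, SGF = 3, SIF = 7)[[fluid]]
}
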