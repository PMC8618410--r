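# Exposure and health-risk arithmetic: estimated daily intake (EDI),
# target hazard quotients (THQ, TTHQ), incremental lifetime cancer risk
# (ILCR), percent-of-reference intake, and the worst-case LOQ
# substitution policy.

#' Estimated daily intake of an element
#'
#' `EDI = (EF * ED * FIR * MC) / (BW * AT)` in mg per kg body weight per
#' day, with MC the element concentration in mg/g dry weight.  The
#' averaging time is `at_noncarc` (by convention `ED * 365`, making the
#' prefactor 1) for non-carcinogenic endpoints and `at_carc` (a 70-year
#' lifetime) for carcinogenic ones, so with defaults
#' `EDI_carc / EDI_noncarc = 54/70` exactly.
#'
#' @param mc Element concentration, mg/g dry weight (canonical unit).
#' @param model An [exposure_model()].
#' @param carcinogenic Use the carcinogenic averaging time?
#' @return EDI in mg/kg/d.
#' @export
#' @examples
#' edi(1e-3)                       # 7.67e-3 / 68.5
#' edi(1e-3, carcinogenic = TRUE)  # times 54/70
edi <- function(mc, model = exposure_model(), carcinogenic = FALSE) {
  stopifnot(is.numeric(mc), inherits(model, "exposure_model"),
            is.logical(carcinogenic), length(carcinogenic) == 1)
  if (any(mc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  at <- if (carcinogenic) model$at_carc else model$at_noncarc
  model$ef * model$ed * model$fir * mc / (model$bw * at)
}

#' Target hazard quotient
#'
#' `THQ = EDI / Rfd`; values above 1 indicate unacceptable
#' non-carcinogenic risk.
#'
#' @param edi_nc Non-carcinogenic EDI, mg/kg/d.
#' @param rfd Oral reference dose, mg/kg/d (strictly positive).
#' @return Dimensionless quotient.
#' @export
#' @examples
#' thq(1.1197e-4, 0.0004)
thq <- function(edi_nc, rfd) {
  stopifnot(is.numeric(edi_nc), is.numeric(rfd))
  if (any(is.na(rfd)) || any(rfd <= 0)) {
    stop("a strictly positive reference dose (rfd) is required",
         call. = FALSE)
  }
  if (any(edi_nc < 0, na.rm = TRUE)) {
    stop("EDI must be non-negative", call. = FALSE)
  }
  edi_nc / rfd
}

#' Total target hazard quotient
#'
#' Sum of the per-element THQs of a variety.  At or below 1 the
#' aggregate non-carcinogenic risk is classified acceptable; above 1,
#' unacceptable.
#'
#' @param thqs Named (by element) or unnamed numeric vector of THQs.
#' @return The sum, with attribute `classification` (`"acceptable"` or
#'   `"unacceptable_noncarc"`).
#' @export
#' @examples
#' tthq(c(Al = 0.001, Cd = 0.001, Cr = 0.001, Pb = 0.001, As = 0.001))
tthq <- function(thqs) {
  stopifnot(is.numeric(thqs), length(thqs) >= 1)
  if (any(thqs < 0, na.rm = TRUE)) {
    stop("THQ values must be non-negative", call. = FALSE)
  }
  total <- sum(thqs, na.rm = TRUE)
  structure(total,
            classification = if (total <= 1) "acceptable"
                             else "unacceptable_noncarc")
}

#' Incremental lifetime cancer risk
#'
#' `ILCR = EDI * CSF` with the carcinogenic-averaging-time EDI.  Risks
#' between 1e-6 and 1e-4 are conventionally tolerable; above 1e-4,
#' intolerable.  Elements without a slope factor (Al) have no defined
#' ILCR; passing `csf = NA` returns `NA` so callers can exclude them.
#'
#' @param edi_c Carcinogenic EDI, mg/kg/d.
#' @param csf Cancer slope factor, (mg/kg/d)^-1, or `NA`.
#' @return Dimensionless risk (or `NA`), with attribute
#'   `classification` (`"tolerable_carc"` / `"intolerable_carc"`).
#' @export
#' @examples
#' ilcr(8.638e-5, 1.5)
ilcr <- function(edi_c, csf) {
  stopifnot(is.numeric(edi_c), is.numeric(csf))
  if (any(edi_c < 0, na.rm = TRUE)) {
    stop("EDI must be non-negative", call. = FALSE)
  }
  if (any(csf < 0, na.rm = TRUE)) {
    stop("cancer slope factors must be non-negative", call. = FALSE)
  }
  risk <- edi_c * csf
  structure(risk,
            classification = ifelse(is.na(risk), NA_character_,
                                    ifelse(risk > 1e-4, "intolerable_carc",
                                           "tolerable_carc")))
}

#' Intake as a percentage of a reference daily dose
#'
#' `100 * daily_intake / reference_daily`.  The default reference for an
#' element is `rfd * bw` (the reference dose scaled to the consumer's
#' body weight).
#'
#' @param daily_intake Element intake, mg/d.
#' @param reference_daily Reference daily dose, mg/d (strictly
#'   positive).
#' @return Percentage.
#' @export
#' @examples
#' pct_of_reference(0.0137, 0.0004 * 68.5)
pct_of_reference <- function(daily_intake, reference_daily) {
  stopifnot(is.numeric(daily_intake), is.numeric(reference_daily))
  if (any(reference_daily <= 0, na.rm = TRUE)) {
    stop("reference daily dose must be strictly positive", call. = FALSE)
  }
  if (any(daily_intake < 0, na.rm = TRUE)) {
    stop("intake must be non-negative", call. = FALSE)
  }
  100 * daily_intake / reference_daily
}

#' Worst-case LOQ substitution
#'
#' Replaces element concentrations below the registered limit of
#' quantification — and missing values — by the LOQ itself, the
#' worst-case exposure convention for censored measurements.  Each
#' substitution is marked in the logical `loq_substituted` column.
#'
#' @param samples Long sample tibble (`variety`, `preparation`,
#'   `replicate`, `element`, `value`, `unit`).
#' @param params Element parameter table with `loq` and `loq_unit`
#'   columns ([element_params()] carries `NA` LOQs by default: supply
#'   instrument-specific limits to enable substitution).
#' @param elements Elements the policy applies to (default: all with a
#'   registered LOQ).
#' @return `samples` with substituted values and a `loq_substituted`
#'   column.  A below-LOQ or missing value for an element without a
#'   registered LOQ is an error.
#' @export
loq_substitute <- function(samples, params, elements = NULL) {
  samples <- validate_samples(samples)
  params <- validate_element_params(params)
  if (is.null(elements)) {
    elements <- params$element[!is.na(params$loq)]
  }
  elements <- normalize_element(elements)
  samples$loq_substituted <- FALSE
  idx <- which(samples$element %in% elements)
  if (length(idx) == 0) return(samples)
  pmatch_ <- match(samples$element[idx], params$element)
  loq <- params$loq[pmatch_]
  loq_unit <- params$loq_unit[pmatch_]
  if (any(is.na(loq))) {
    stop("no registered LOQ for element(s): ",
         paste(unique(samples$element[idx][is.na(loq)]), collapse = ", "),
         call. = FALSE)
  }
  # compare in the sample's own unit; an unstated LOQ unit means the
  # canonical one
  loq_unit[is.na(loq_unit)] <- "mg/g"
  loq_in_sample_unit <- convert_concentration(loq, loq_unit,
                                              samples$unit[idx])
  below <- is.na(samples$value[idx]) | samples$value[idx] < loq_in_sample_unit
  samples$value[idx][below] <- loq_in_sample_unit[below]
  samples$loq_substituted[idx][below] <- TRUE
  samples
}

#' Per-variety health-risk assessment
#'
#' Runs the full risk chain on a long sample table: converts
#' concentrations to mg/g dry weight, averages replicates per variety
#' and element, computes non-carcinogenic and carcinogenic EDIs, THQ,
#' ILCR and percent-of-reference per element, then aggregates TTHQ and
#' total ILCR per variety with their risk classifications.
#'
#' @param samples Long sample tibble; only rows with
#'   `preparation == preparation` are used.
#' @param params Element parameter table ([element_params()]).  Elements
#'   present in the samples but absent from the table are an error.
#' @param model An [exposure_model()].
#' @param preparation Which preparation to assess (`"digestible"` by
#'   default: risk from what the gut can absorb).
#' @return A list with class `risk_assessment`:
#'   * `per_element`: tibble `variety`, `element`, `mc_mg_per_g`,
#'     `edi_nc`, `edi_c`, `thq`, `ilcr`, `pct_of_reference`;
#'   * `per_variety`: tibble `variety`, `tthq`, `ilcr_total`,
#'     `classification_noncarc`, `classification_carc`.
#' @export
#' @examples
#' samples <- rice_metal_samples("digestible", reinterpret = "ug/g")
#' risk <- assess_risk(samples)
#' risk$per_variety
assess_risk <- function(samples, params = element_params(),
                        model = exposure_model(),
                        preparation = "digestible") {
  samples <- validate_samples(samples)
  params <- validate_element_params(params)
  stopifnot(length(preparation) == 1)
  use <- samples[samples$preparation == preparation, ]
  if (nrow(use) == 0) {
    stop("no samples with preparation ", sQuote(preparation), call. = FALSE)
  }
  unknown <- setdiff(unique(use$element), params$element)
  if (length(unknown) > 0) {
    stop("no toxicological parameters for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per_element <- use |>
    dplyr::mutate(mc = as_mg_per_g(.data$value, .data$unit)) |>
    dplyr::group_by(.data$variety, .data$element) |>
    dplyr::summarise(mc_mg_per_g = mean(.data$mc), .groups = "drop") |>
    dplyr::left_join(params[, c("element", "rfd", "csf")], by = "element") |>
    dplyr::mutate(
      edi_nc = edi(.data$mc_mg_per_g, model, carcinogenic = FALSE),
      edi_c = edi(.data$mc_mg_per_g, model, carcinogenic = TRUE),
      thq = .data$edi_nc / .data$rfd,
      ilcr = .data$edi_c * .data$csf,
      pct_of_reference = pct_of_reference(
        .data$mc_mg_per_g * model$fir, .data$rfd * model$bw)
    ) |>
    dplyr::select("variety", "element", "mc_mg_per_g", "edi_nc",
                  "edi_c", "thq", "ilcr", "pct_of_reference")
  per_variety <- per_element |>
    dplyr::group_by(.data$variety) |>
    dplyr::summarise(
      tthq = sum(.data$thq),
      ilcr_total = sum(.data$ilcr, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      classification_noncarc = ifelse(.data$tthq <= 1, "acceptable",
                                      "unacceptable_noncarc"),
      classification_carc = ifelse(.data$ilcr_total > 1e-4,
                                   "intolerable_carc", "tolerable_carc")
    )
  structure(list(per_element = per_element, per_variety = per_variety,
                 preparation = preparation, model = model),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("Health-risk assessment (", x$preparation, " fraction)\n", sep = "")
  cat(sprintf("  %d varieties, %d element records\n",
              nrow(x$per_variety), nrow(x$per_element)))
  cat(sprintf("  max TTHQ: %.3g  |  max total ILCR: %.3g\n",
              max(x$per_variety$tthq), max(x$per_variety$ilcr_total)))
  print(x$per_variety, n = 5)
  invisible(x)
}
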