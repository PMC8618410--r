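# Toxicological parameter registries and the exposure model.

#' Toxicological parameters for the studied elements
#'
#' Default registry of per-element constants used by the risk equations:
#' the oral reference dose Rfd (mg per kg body weight per day) for the
#' non-carcinogenic hazard quotient, and the USEPA cancer slope factor
#' CSF (per mg/kg/d) for the incremental lifetime cancer risk.  Al has
#' no slope factor, so no ILCR is defined for it.  Limits of
#' quantification (LOQ) are instrument-specific and are therefore `NA`
#' by default; supply them to enable worst-case substitution with
#' [loq_substitute()].
#'
#' @param elements Optional character vector restricting the registry to
#'   a subset of elements.
#' @return A tibble with columns `element`, `rfd`, `csf`, `loq`,
#'   `loq_unit`.
#' @export
#' @examples
#' element_params()
#' element_params(c("As", "Cd"))
element_params <- function(elements = NULL) {
  reg <- tibble::tibble(
    element = c("Al", "Cr", "As", "Cd", "Pb"),
    rfd = c(0.0004, 0.0030, 0.0003, 0.0010, 0.0035),
    csf = c(NA_real_, 0.5000, 1.5000, 0.3800, 0.0085),
    loq = NA_real_,
    loq_unit = NA_character_
  )
  if (!is.null(elements)) {
    elements <- normalize_element(elements)
    missing <- setdiff(elements, reg$element)
    if (length(missing) > 0) {
      stop("no registered parameters for element(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    reg <- reg[match(elements, reg$element), ]
  }
  validate_element_params(reg)
}

validate_element_params <- function(params) {
  stopifnot(is.data.frame(params))
  required <- c("element", "rfd")
  miss <- setdiff(required, names(params))
  if (length(miss) > 0) {
    stop("element parameter table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"csf" %in% names(params)) params$csf <- NA_real_
  if (!"loq" %in% names(params)) params$loq <- NA_real_
  if (!"loq_unit" %in% names(params)) params$loq_unit <- NA_character_
  if (anyDuplicated(params$element)) {
    stop("duplicated element in parameter table", call. = FALSE)
  }
  if (any(!is.na(params$rfd) & params$rfd <= 0)) {
    stop("reference doses (rfd) must be strictly positive", call. = FALSE)
  }
  if (any(!is.na(params$csf) & params$csf < 0)) {
    stop("cancer slope factors (csf) must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(params)
}

# Chemical symbols are stored capitalized ("As", "Cd", ...); inputs in
# any case are normalized so CSV files can be sloppy about it.
normalize_element <- function(element) {
  e <- trimws(as.character(element))
  paste0(toupper(substr(e, 1, 1)), tolower(substring(e, 2)))
}

#' Population exposure model
#'
#' Bundle of exposure constants entering the estimated daily intake:
#' food ingestion rate `fir` (g/person/d), body weight `bw` (kg),
#' exposure frequency `ef` (d/y), exposure duration `ed` (y), and the
#' averaging times (d) for non-carcinogenic (`at_noncarc`, by convention
#' `ed * 365`) and carcinogenic effects (`at_carc`, a 70-year lifetime).
#' Defaults describe an adult Spanish rice consumer: 7.67 g/d intake,
#' 68.5 kg body weight, 365 d/y over 54 years.
#'
#' With the default values `ef * ed / at_noncarc` is exactly 1, so the
#' non-carcinogenic intake reduces to `fir * mc / bw`; the full form is
#' kept so any parameter can be varied.
#'
#' @param fir Food ingestion rate, g/person/d.
#' @param bw Body weight, kg.
#' @param ef Exposure frequency, d/y.
#' @param ed Exposure duration, y.
#' @param at_noncarc Averaging time for non-carcinogenic effects, d.
#' @param at_carc Averaging time for carcinogenic effects, d.
#' @return An object of class `exposure_model` (a named list).
#' @export
#' @examples
#' exposure_model()
#' exposure_model(bw = 60)
exposure_model <- function(fir = 7.67, bw = 68.5, ef = 365, ed = 54,
                           at_noncarc = ed * 365, at_carc = 70 * 365) {
  m <- list(fir = fir, bw = bw, ef = ef, ed = ed,
            at_noncarc = at_noncarc, at_carc = at_carc)
  bad <- names(m)[!vapply(m, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    stop("exposure model fields must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(m, class = "exposure_model")
}

#' @export
print.exposure_model <- function(x, ...) {
  cat("Exposure model\n")
  cat(sprintf("  ingestion rate (FIR): %g g/person/d\n", x$fir))
  cat(sprintf("  body weight (BW):     %g kg\n", x$bw))
  cat(sprintf("  frequency (EF):       %g d/y\n", x$ef))
  cat(sprintf("  duration (ED):        %g y\n", x$ed))
  cat(sprintf("  averaging time:       %g d (non-carc), %g d (carc)\n",
              x$at_noncarc, x$at_carc))
  invisible(x)
}

#' Build a sample manifest for a measurement design
#'
#' Enumerates the full crossing of varieties, preparations, and
#' replicates of a study design.  The design behind the packaged data is
#' 14 varieties of cooked and digested rice in triplicate (84 analyzed
#' samples).
#'
#' @param varieties Number of varieties, or a character vector of
#'   variety names.
#' @param preparations Character vector drawn from `"raw"`, `"cooked"`,
#'   `"digestible"`, `"non_digestible"`.
#' @param n_replicates Replicates per variety and preparation.
#' @return A tibble with one row per planned sample: `variety`,
#'   `preparation`, `replicate`.
#' @export
#' @examples
#' nrow(build_manifest(14, c("cooked", "digestible"), 3))  # 84
build_manifest <- function(varieties, preparations, n_replicates) {
  if (is.numeric(varieties)) {
    stopifnot(length(varieties) == 1, varieties >= 1)
    varieties <- sprintf("variety_%02d", seq_len(varieties))
  }
  varieties <- as.character(varieties)
  if (length(varieties) < 1 || anyDuplicated(varieties)) {
    stop("varieties must be a non-empty set of unique names", call. = FALSE)
  }
  preparations <- match.arg(
    as.character(preparations),
    c("raw", "cooked", "digestible", "non_digestible"),
    several.ok = TRUE
  )
  if (length(preparations) < 1) stop("empty preparations list", call. = FALSE)
  if (anyDuplicated(preparations)) {
    stop("preparations must be unique", call. = FALSE)
  }
  stopifnot(is.numeric(n_replicates), length(n_replicates) == 1,
            n_replicates >= 1)
  tidyr::expand_grid(
    variety = varieties,
    preparation = preparations,
    replicate = seq_len(n_replicates)
  )
}
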