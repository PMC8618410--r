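# Bioaccessibility: the share of an element in cooked rice that is
# released into the aqueous-micellar (digestible) phase during simulated
# digestion, and hence available for intestinal absorption.

#' Bioaccessibility percentage
#'
#' `100 * digestible / cooked`, the fraction of the element in cooked
#' rice recovered in the digestible phase.  Inputs must share a unit
#' (the ratio is unit-free).  Values above 100% — possible with rounded
#' or noisy inputs — are returned with a warning and marked in the
#' `"flagged"` attribute rather than rejected.
#'
#' @param digestible,cooked Element amounts (or concentrations) in the
#'   digestible fraction and in cooked rice, same units.
#' @return Percentage vector with logical attribute `flagged` marking
#'   entries above 100.
#' @export
#' @examples
#' bioaccessibility_pct(1.3e-3, 2.8e-3)
bioaccessibility_pct <- function(digestible, cooked) {
  stopifnot(is.numeric(digestible), is.numeric(cooked))
  if (any(digestible < 0, na.rm = TRUE)) {
    stop("digestible amounts must be non-negative", call. = FALSE)
  }
  if (any(cooked <= 0, na.rm = TRUE)) {
    stop("bioaccessibility undefined for non-positive cooked amount",
         call. = FALSE)
  }
  pct <- 100 * digestible / cooked
  flagged <- !is.na(pct) & pct > 100
  if (any(flagged)) {
    warning("bioaccessibility above 100% (digestible exceeds cooked); ",
            "flagged, not an error", call. = FALSE)
  }
  structure(pct, flagged = flagged)
}

#' Digestible concentration by subtraction
#'
#' When the digestible phase was not measured directly, its element
#' concentration can be estimated as cooked minus non-digestible.
#' Negative differences (noise) are clamped to zero and flagged.
#'
#' @param cooked,non_digestible Concentrations in the same unit.
#' @return Estimated digestible concentration with attribute `clamped`.
#' @export
#' @examples
#' digestible_by_subtraction(2.5e-3, 1.7e-3)
digestible_by_subtraction <- function(cooked, non_digestible) {
  stopifnot(is.numeric(cooked), is.numeric(non_digestible))
  if (any(cooked < 0, na.rm = TRUE) ||
      any(non_digestible < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  value <- cooked - non_digestible
  clamped <- !is.na(value) & value < 0
  if (any(clamped)) {
    warning("non-digestible exceeds cooked concentration; clamped to 0",
            call. = FALSE)
    value[clamped] <- 0
  }
  structure(value, clamped = clamped)
}

#' Per-variety bioaccessibility table
#'
#' Computes element bioaccessibility for every variety from a long
#' sample table containing `cooked` records and either measured
#' `digestible` records (`route = "measured"`) or `non_digestible`
#' records to subtract (`route = "subtraction"`).  Replicates are paired
#' by index when both preparations carry the same replicate ids,
#' otherwise variety means are compared.
#'
#' @param samples Long sample tibble (`variety`, `preparation`,
#'   `replicate`, `element`, `value`, `unit`).
#' @param route `"measured"` or `"subtraction"`.
#' @param exclude_over_100 Drop flagged (>100%) values from the
#'   summarised mean (they are still listed per replicate).
#' @return A tibble `variety`, `element`, `n`, `pct`, `sd`, `route`,
#'   `n_flagged`.
#' @export
bioaccessibility_table <- function(samples,
                                   route = c("measured", "subtraction"),
                                   exclude_over_100 = TRUE) {
  route <- match.arg(route)
  samples <- validate_samples(samples)
  need <- if (route == "measured") "digestible" else "non_digestible"
  wide <- samples |>
    dplyr::filter(.data$preparation %in% c("cooked", need)) |>
    dplyr::mutate(value = as_mg_per_g(.data$value, .data$unit)) |>
    dplyr::select("variety", "preparation", "replicate", "element",
                  "value") |>
    tidyr::pivot_wider(names_from = "preparation",
                       values_from = "value")
  if (!all(c("cooked", need) %in% names(wide))) {
    stop("samples must contain 'cooked' and '", need, "' records",
         call. = FALSE)
  }
  wide <- tidyr::drop_na(wide, dplyr::all_of(c("cooked", need)))
  dig <- if (route == "measured") wide$digestible else
    suppressWarnings(as.numeric(
      digestible_by_subtraction(wide$cooked, wide$non_digestible)))
  pct <- suppressWarnings(bioaccessibility_pct(dig, wide$cooked))
  wide$pct <- as.numeric(pct)
  wide$flagged <- attr(pct, "flagged")
  wide |>
    dplyr::group_by(.data$variety, .data$element) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_flagged = sum(.data$flagged),
      sd = stats::sd(.data$pct[!(exclude_over_100 & .data$flagged)]),
      pct = mean(.data$pct[!(exclude_over_100 & .data$flagged)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(route = route) |>
    dplyr::select("variety", "element", "n", "pct", "sd", "route",
                  "n_flagged")
}
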