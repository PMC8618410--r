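# Digestible / non-digestible fraction bookkeeping.  Simulated
# digestion followed by centrifugation splits cooked rice into an
# aqueous-micellar (digestible) phase and a pellet (non-digestible
# fraction); these helpers account for the split, convert as-is
# percentages to a dry-weight basis, and estimate how much protein the
# digestible fraction carries.

#' Fraction split from recovered masses
#'
#' Percentages of the cooked dry mass ending up in the non-digestible
#' pellet and the digestible phase.
#'
#' @param mass_nd,mass_d Recovered masses (g) of the non-digestible and
#'   digestible fractions; non-negative, not both zero.
#' @return A list of class `fraction_split` with `non_digestible_pct`
#'   and `digestible_pct` (they sum to 100).
#' @export
#' @examples
#' fraction_split(7.31, 2.69)  # 73.1% non-digestible
fraction_split <- function(mass_nd, mass_d) {
  stopifnot(is.numeric(mass_nd), is.numeric(mass_d),
            length(mass_nd) == 1, length(mass_d) == 1)
  if (mass_nd < 0 || mass_d < 0) {
    stop("fraction masses must be non-negative", call. = FALSE)
  }
  total <- mass_nd + mass_d
  if (total == 0) {
    stop("cannot split a zero total mass", call. = FALSE)
  }
  structure(
    list(non_digestible_pct = 100 * mass_nd / total,
         digestible_pct = 100 * mass_d / total),
    class = "fraction_split"
  )
}

# accept either a fraction_split or a bare non-digestible percentage
as_fraction_split <- function(x) {
  if (inherits(x, "fraction_split")) return(x)
  if (is.numeric(x) && length(x) == 1 && x >= 0 && x <= 100) {
    return(structure(list(non_digestible_pct = x,
                          digestible_pct = 100 - x),
                     class = "fraction_split"))
  }
  stop("expected a fraction_split or a non-digestible percentage in [0, 100]",
       call. = FALSE)
}

#' @export
print.fraction_split <- function(x, ...) {
  cat(sprintf("Fraction split: %.1f%% non-digestible / %.1f%% digestible\n",
              x$non_digestible_pct, x$digestible_pct))
  invisible(x)
}

#' Convert an as-is percentage to a dry-weight basis
#'
#' @param value_pct Component percentage of the wet sample.
#' @param moisture_pct Moisture percentage in `[0, 100)`.
#' @return The percentage referred to the moisture-free mass:
#'   `value_pct / (1 - moisture_pct / 100)`.
#' @export
#' @examples
#' to_dry_weight(9.60, 14.17)
to_dry_weight <- function(value_pct, moisture_pct) {
  stopifnot(is.numeric(value_pct), is.numeric(moisture_pct))
  if (any(moisture_pct < 0 | moisture_pct >= 100)) {
    stop("moisture percentage must lie in [0, 100)", call. = FALSE)
  }
  value_pct / (1 - moisture_pct / 100)
}

#' Protein content of the digestible fraction by mass balance
#'
#' The protein carried by the digestible phase is what remains of the
#' cooked-rice protein after removing the protein retained in the
#' non-digestible pellet, referred to the digestible mass:
#' `(cooked_protein - f_nd * nd_protein) / f_d`, with the fractions as
#' proportions.  Measurement noise can push the balance negative; such
#' values are clamped to zero and flagged via the `"clamped"` attribute
#' and a warning.
#'
#' @param cooked_protein_pct Protein in cooked rice, % dry weight.
#' @param split A [fraction_split()] (or bare non-digestible %).
#' @param nd_protein_pct Protein in the non-digestible fraction, % of
#'   that fraction's mass.
#' @return Protein as % of the digestible mass, with attribute
#'   `clamped` (logical).
#' @export
#' @examples
#' digestible_protein(10.97, fraction_split(7.31, 2.69), 10.29)
digestible_protein <- function(cooked_protein_pct, split, nd_protein_pct) {
  split <- as_fraction_split(split)
  stopifnot(is.numeric(cooked_protein_pct), is.numeric(nd_protein_pct))
  if (any(cooked_protein_pct < 0) || any(nd_protein_pct < 0)) {
    stop("protein percentages must be non-negative", call. = FALSE)
  }
  f_nd <- split$non_digestible_pct / 100
  f_d <- split$digestible_pct / 100
  if (f_d == 0) {
    stop("digestible fraction is zero; protein balance undefined",
         call. = FALSE)
  }
  value <- (cooked_protein_pct - f_nd * nd_protein_pct) / f_d
  clamped <- value < 0
  if (any(clamped)) {
    warning("protein mass balance went negative; clamped to 0",
            call. = FALSE)
    value[clamped] <- 0
  }
  structure(value, clamped = clamped)
}

#' Protein liberated per 100 g of cooked rice
#'
#' Grams of protein made available for absorption by eating 100 g of
#' cooked rice: the digestible mass fraction times its protein content.
#'
#' @param split A [fraction_split()] (or bare non-digestible %).
#' @param d_protein_pct Protein in the digestible fraction, % of its
#'   mass.
#' @return Grams of liberated protein per 100 g cooked rice.
#' @export
#' @examples
#' protein_liberation(fraction_split(7.31, 2.69), 5.77)
protein_liberation <- function(split, d_protein_pct) {
  split <- as_fraction_split(split)
  stopifnot(is.numeric(d_protein_pct))
  if (any(d_protein_pct < 0)) {
    stop("protein percentage must be non-negative", call. = FALSE)
  }
  split$digestible_pct / 100 * d_protein_pct
}
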