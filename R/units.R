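# Concentration unit handling.
#
# Canonical internal unit is mg of element per g of rice dry weight
# ("mg/g"): the intake equation takes MC in mg/g and the reference doses
# are in mg per kg body weight per day, so keeping everything in mg/g
# makes the risk arithmetic dimensionally transparent.  All supported
# units differ from mg/g by exact powers of ten, so conversions are
# lossless and round-trip exactly.

# decimal exponent of each unit relative to mg/g
.unit_exponent <- c(
  "ng/g"  = -6,
  "ug/g"  = -3,
  "mg/kg" = -3,
  "mg/g"  = 0
)
.unit_to_mg_per_g <- 10^.unit_exponent

#' Supported concentration units
#'
#' Units accepted throughout the package for element concentrations in
#' rice.  `"mg/kg"` and `"ug/g"` are synonyms (both 1e-3 mg/g); the
#' canonical internal unit is `"mg/g"` dry weight.
#'
#' @return Character vector of unit names.
#' @export
#' @examples
#' concentration_units()
concentration_units <- function() names(.unit_to_mg_per_g)

# Accept common spellings ("µg/g", "ppb", ...) and map them onto the
# canonical unit labels.  Unknown units raise an error naming the unit.
normalize_unit <- function(unit) {
  u <- trimws(tolower(as.character(unit)))
  u[u %in% c("µg/g", "μg/g", "mcg/g", "ppm")] <- "ug/g"
  u[u %in% c("ppb")] <- "ng/g"
  bad <- unique(u[!u %in% names(.unit_to_mg_per_g)])
  if (length(bad) > 0) {
    stop("unsupported concentration unit(s): ",
         paste(sQuote(bad), collapse = ", "),
         "; supported units are ",
         paste(sQuote(names(.unit_to_mg_per_g)), collapse = ", "),
         call. = FALSE)
  }
  u
}

#' Convert element concentrations between mass-ratio units
#'
#' All supported units are exact powers of ten apart, so the conversion
#' is a single multiplication and round-trips exactly.  The dry-weight
#' basis of a value is not altered by unit conversion.
#'
#' @param value Numeric vector of non-negative concentrations.
#' @param from,to Unit names (see [concentration_units()]); vectors are
#'   recycled against `value`.
#' @return Numeric vector of concentrations expressed in `to`.
#' @export
#' @examples
#' convert_concentration(1, "ug/g", "mg/g")     # 0.001
#' convert_concentration(2.5e-3, "ng/g", "mg/g")
convert_concentration <- function(value, from, to) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  d <- .unit_exponent[from] - .unit_exponent[to]
  # scale by the integer power of ten, dividing rather than multiplying
  # by sub-unit factors so that round trips are exact
  unname(value * 10^pmax(d, 0) / 10^pmax(-d, 0))
}

#' @rdname convert_concentration
#' @export
as_mg_per_g <- function(value, from) {
  unname(convert_concentration(value, from, "mg/g"))
}
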