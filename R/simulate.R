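# Synthetic-study generator.  Emulates the measurement design of the
# packaged survey — varieties x replicates, cooked and digested — with
# the distributional structure the analysis assumes: lognormal element
# concentrations across varieties, multiplicative replicate noise,
# beta-distributed per-element bioaccessibility, and a beta-distributed
# digestible/non-digestible mass split.  Ground truth is recorded so
# recovery can be tested.

#' Configuration for a synthetic digestion study
#'
#' Defaults mirror the packaged 14-variety survey: triplicate
#' measurements, a non-digestible mass fraction of 0.443 +/- 0.129
#' across varieties, element geometric means inside the measured cooked
#' ranges (canonical mg/g dry weight, under the ug/g reading of the
#' survey tables), and mean bioaccessibilities near the measured
#' per-element averages.
#'
#' @param n_varieties Number of varieties.
#' @param n_replicates Replicates per variety and preparation.
#' @param element_gm Named vector of geometric-mean cooked
#'   concentrations, mg/g dry weight.
#' @param element_gsd Named vector (or scalar) of geometric SDs across
#'   varieties, >= 1.
#' @param replicate_cv Multiplicative replicate-level coefficient of
#'   variation (lognormal sdlog), >= 0.
#' @param nd_fraction_mean,nd_fraction_sd Mean and SD of the
#'   non-digestible mass proportion across varieties (beta-distributed).
#' @param bioaccessibility_mean Named vector of mean bioaccessible
#'   proportions per element (beta-distributed across varieties).
#' @param bioaccessibility_kappa Beta precision (alpha + beta) of the
#'   bioaccessibility distribution.
#' @param composition_means Named vector of mean composition
#'   percentages (must sum to <= 100).
#' @param composition_cv Relative SD of composition components across
#'   varieties.
#' @return A validated list of class `simulation_config`.
#' @export
#' @examples
#' simulation_config(n_varieties = 4, n_replicates = 2)
simulation_config <- function(
    n_varieties = 14,
    n_replicates = 3,
    element_gm = c(Al = 2.3e-6, Cd = 1.8e-8, Cr = 4.5e-8,
                   Pb = 1.8e-8, As = 3.6e-8),
    element_gsd = 1.15,
    replicate_cv = 0.10,
    nd_fraction_mean = 0.443,
    nd_fraction_sd = 0.129,
    bioaccessibility_mean = c(Al = 0.63, Cd = 0.56, Cr = 0.40,
                              Pb = 0.56, As = 0.49),
    bioaccessibility_kappa = 50,
    composition_means = c(moisture = 4.09, ash = 0.48, fat = 0.58,
                          protein = 10.33, carbohydrates = 84.49),
    composition_cv = 0.10) {
  stopifnot(n_varieties >= 1, n_replicates >= 1)
  elements <- names(element_gm)
  if (is.null(elements) || any(elements == "")) {
    stop("element_gm must be a named vector", call. = FALSE)
  }
  if (length(element_gsd) == 1) {
    element_gsd <- stats::setNames(rep(element_gsd, length(elements)),
                                   elements)
  }
  if (!setequal(names(element_gsd), elements) ||
      !setequal(names(bioaccessibility_mean), elements)) {
    stop("element_gsd and bioaccessibility_mean must cover the same ",
         "elements as element_gm", call. = FALSE)
  }
  if (any(element_gm <= 0)) stop("element_gm must be positive", call. = FALSE)
  if (any(element_gsd < 1)) stop("element_gsd must be >= 1", call. = FALSE)
  if (replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  if (nd_fraction_mean <= 0 || nd_fraction_mean >= 1) {
    stop("nd_fraction_mean must lie in (0, 1)", call. = FALSE)
  }
  max_sd <- sqrt(nd_fraction_mean * (1 - nd_fraction_mean))
  if (nd_fraction_sd < 0 || nd_fraction_sd >= max_sd) {
    stop("nd_fraction_sd must lie in [0, ", signif(max_sd, 3),
         ") for a beta with this mean", call. = FALSE)
  }
  if (any(bioaccessibility_mean <= 0 | bioaccessibility_mean >= 1)) {
    stop("bioaccessibility_mean entries must lie in (0, 1)", call. = FALSE)
  }
  if (bioaccessibility_kappa <= 0) {
    stop("bioaccessibility_kappa must be positive", call. = FALSE)
  }
  if (sum(composition_means) > 100) {
    stop("composition means must sum to <= 100", call. = FALSE)
  }
  if (composition_cv < 0) stop("composition_cv must be >= 0", call. = FALSE)
  structure(
    list(n_varieties = as.integer(n_varieties),
         n_replicates = as.integer(n_replicates),
         elements = elements,
         element_gm = element_gm[elements],
         element_gsd = element_gsd[elements],
         replicate_cv = replicate_cv,
         nd_fraction_mean = nd_fraction_mean,
         nd_fraction_sd = nd_fraction_sd,
         bioaccessibility_mean = bioaccessibility_mean[elements],
         bioaccessibility_kappa = bioaccessibility_kappa,
         composition_means = composition_means,
         composition_cv = composition_cv),
    class = "simulation_config")
}

# method-of-moments beta parameters; degenerate sd = 0 handled upstream
beta_moments <- function(mean, sd) {
  if (sd == 0) return(NULL)
  kappa <- mean * (1 - mean) / sd^2 - 1
  if (kappa <= 0) stop("beta variance too large for this mean", call. = FALSE)
  c(shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
}

rbeta_ms <- function(n, mean, sd) {
  par <- beta_moments(mean, sd)
  if (is.null(par)) return(rep(mean, n))
  stats::rbeta(n, par["shape1"], par["shape2"])
}

#' Generate a synthetic digestion study
#'
#' Draws a complete study under `config`: per variety and element a
#' cooked geometric-mean concentration (lognormal across varieties),
#' replicate cooked values with multiplicative noise, a per-variety and
#' per-element bioaccessible proportion (beta), digestible replicate
#' concentrations as `cooked * bioaccessibility`, and non-digestible as
#' the exact remainder (so digestible + non-digestible = cooked for
#' every record).  Per-variety mass splits and composition profiles are
#' drawn independently.
#'
#' Sampling uses R's Mersenne-Twister generator seeded with `seed`, so a
#' fixed seed reproduces the study exactly.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_study`:
#'   * `samples`: long tibble (`variety`, `preparation`, `replicate`,
#'     `element`, `value`, `unit`), preparations `cooked`, `digestible`,
#'     `non_digestible`, canonical mg/g;
#'   * `splits`: tibble `variety`, `non_digestible_pct`,
#'     `digestible_pct`;
#'   * `composition`: tibble `variety`, `component`, `value`;
#'   * `truth`: list with the variety-level draws and the generating
#'     config.
#' @export
#' @examples
#' study <- generate_study(simulation_config(n_varieties = 3), seed = 1)
#' head(study$samples)
generate_study <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"),
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  nv <- config$n_varieties
  nr <- config$n_replicates
  el <- config$elements
  varieties <- sprintf("variety_%03d", seq_len(nv))

  # variety-level cooked geometric means, lognormal across varieties
  gm <- outer(rep(1, nv), config$element_gm) *
    exp(matrix(stats::rnorm(nv * length(el)), nv) *
          outer(rep(1, nv), log(config$element_gsd)))
  dimnames(gm) <- list(varieties, el)

  # variety-level bioaccessible proportion per element
  b <- sapply(el, function(e) {
    m <- config$bioaccessibility_mean[[e]]
    k <- config$bioaccessibility_kappa
    stats::rbeta(nv, m * k, (1 - m) * k)
  })
  dimnames(b) <- list(varieties, el)

  # replicate-level cooked values with multiplicative noise
  grid <- tidyr::expand_grid(variety = varieties, element = el,
                             replicate = seq_len(nr))
  noise <- if (config$replicate_cv == 0) rep(1, nrow(grid)) else
    exp(stats::rnorm(nrow(grid), 0, config$replicate_cv))
  cooked <- gm[cbind(grid$variety, grid$element)] * noise
  digestible <- cooked * b[cbind(grid$variety, grid$element)]
  non_digestible <- cooked - digestible

  samples <- dplyr::bind_rows(
    tibble::tibble(variety = grid$variety, preparation = "cooked",
                   replicate = grid$replicate, element = grid$element,
                   value = cooked, unit = "mg/g"),
    tibble::tibble(variety = grid$variety, preparation = "digestible",
                   replicate = grid$replicate, element = grid$element,
                   value = digestible, unit = "mg/g"),
    tibble::tibble(variety = grid$variety, preparation = "non_digestible",
                   replicate = grid$replicate, element = grid$element,
                   value = non_digestible, unit = "mg/g")
  )

  nd <- rbeta_ms(nv, config$nd_fraction_mean, config$nd_fraction_sd)
  splits <- tibble::tibble(variety = varieties,
                           non_digestible_pct = 100 * nd,
                           digestible_pct = 100 * (1 - nd))

  comp <- config$composition_means
  comp_draw <- sapply(names(comp), function(cmp) {
    pmax(stats::rnorm(nv, comp[[cmp]], config$composition_cv * comp[[cmp]]),
         0)
  })
  composition <- tibble::tibble(
    variety = rep(varieties, times = length(comp)),
    component = rep(names(comp), each = nv),
    value = as.vector(comp_draw)
  )

  structure(
    list(samples = samples, splits = splits, composition = composition,
         truth = list(config = config, seed = as.integer(seed),
                      variety_gm = gm, bioaccessibility = b,
                      nd_fraction = nd)),
    class = "synthetic_study")
}

#' Recover generator parameters from a synthetic study
#'
#' Method-of-moments estimates of the quantities the generator drew
#' from: per-element geometric-mean cooked concentration (mean of
#' variety log-means), per-element mean bioaccessible proportion (mean
#' of the variety-level digestible/cooked ratios), and the mean
#' non-digestible mass proportion.  Standard errors are the empirical
#' SEs of the variety-level quantities.
#'
#' @param study A [generate_study()] result.
#' @return A list with tibbles `element_gm` (`element`, `estimate`,
#'   `se`), `bioaccessibility` (`element`, `estimate`, `se`) and a
#'   one-row tibble `nd_fraction` (`estimate`, `se`).
#' @export
recover_parameters <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  s <- study$samples
  wide <- s |>
    dplyr::filter(.data$preparation %in% c("cooked", "digestible")) |>
    tidyr::pivot_wider(names_from = "preparation", values_from = "value")
  by_var <- wide |>
    dplyr::group_by(.data$element, .data$variety) |>
    dplyr::summarise(log_gm = mean(log(.data$cooked)),
                     ratio = mean(.data$digestible / .data$cooked),
                     .groups = "drop")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  element_gm <- by_var |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(
      estimate = exp(mean(.data$log_gm)),
      se = exp(mean(.data$log_gm)) * se(.data$log_gm),
      .groups = "drop")
  bioaccessibility <- by_var |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(estimate = mean(.data$ratio), se = se(.data$ratio),
                     .groups = "drop")
  nd <- study$splits$non_digestible_pct / 100
  list(element_gm = element_gm,
       bioaccessibility = bioaccessibility,
       nd_fraction = tibble::tibble(estimate = mean(nd), se = se(nd)))
}
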