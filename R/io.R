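# Readers, writers, and the end-to-end analysis driver.  The single
# input dialect is a long (tidy) CSV — one row per variety, preparation,
# replicate, and element — because wide tables are ambiguous to parse;
# wide layouts are outputs only.

.valid_preparations <- c("raw", "cooked", "digestible", "non_digestible")

#' Validate a long sample table
#'
#' Checks the column contract of the long sample format (`variety`,
#' `preparation`, `replicate`, `element`, `value`, `unit`), normalizes
#' element symbols and units, and rejects duplicate
#' (variety, preparation, replicate, element) keys.
#'
#' @param samples A data frame in the long sample format.
#' @return The validated tibble (element symbols and units normalized).
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("variety", "preparation", "replicate", "element", "value",
            "unit")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  samples$element <- normalize_element(samples$element)
  samples$unit <- normalize_unit(samples$unit)
  bad_prep <- setdiff(unique(samples$preparation), .valid_preparations)
  if (length(bad_prep) > 0) {
    stop("unknown preparation(s): ", paste(bad_prep, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(samples$value) & samples$value < 0)) {
    stop("negative concentration values", call. = FALSE)
  }
  key <- paste(samples$variety, samples$preparation, samples$replicate,
               samples$element, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (variety, preparation, replicate, element) keys",
         call. = FALSE)
  }
  samples
}

#' Read a long sample CSV
#'
#' Reads and validates a UTF-8, comma-separated sample file with header
#' `variety, preparation, replicate, element, value, unit`.  Malformed
#' rows (unknown unit or preparation, negative or non-numeric value,
#' duplicate key) are dropped and reported — with their line numbers —
#' in the `"problems"` attribute of the result; use `strict = TRUE` to
#' turn any problem into an error.
#'
#' @param path CSV file path.
#' @param strict Fail on any invalid row instead of collecting them.
#' @return A validated sample tibble with attribute `problems` (tibble
#'   `line`, `message`).
#' @export
read_samples <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("variety", "preparation", "replicate", "element", "value",
            "unit")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("sample file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw <- tibble::as_tibble(raw)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  problems <- list()
  flag <- function(idx, msg) {
    if (any(idx)) {
      problems[[length(problems) + 1L]] <<-
        tibble::tibble(line = line[idx], message = msg)
    }
    idx
  }
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- flag(is.na(value) & !is.na(raw$value) & raw$value != "",
              "non-numeric value")
  bad <- bad | flag(!is.na(value) & value < 0, "negative value")
  unit_ok <- tryCatch({
    normalize_unit(raw$unit)
    rep(TRUE, nrow(raw))
  }, error = function(e) {
    vapply(raw$unit, function(u)
      !inherits(tryCatch(normalize_unit(u), error = identity),
                "error"), logical(1))
  })
  bad <- bad | flag(!unit_ok, "unknown unit")
  bad <- bad | flag(!raw$preparation %in% .valid_preparations,
                    "unknown preparation")
  key <- paste(raw$variety, raw$preparation, raw$replicate, raw$element,
               sep = "\r")
  bad <- bad | flag(duplicated(key), "duplicate key")
  problems <- if (length(problems) > 0) {
    dplyr::arrange(dplyr::bind_rows(problems), .data$line)
  } else {
    tibble::tibble(line = integer(), message = character())
  }
  if (strict && nrow(problems) > 0) {
    stop("invalid rows in ", path, ":\n",
         paste(sprintf("  line %d: %s", problems$line, problems$message),
               collapse = "\n"), call. = FALSE)
  }
  keep <- raw[!bad, ]
  keep$value <- value[!bad]
  out <- validate_samples(keep)
  attr(out, "problems") <- problems
  out
}

#' Write a long sample CSV
#'
#' Inverse of [read_samples()]: UTF-8, comma-separated, full numeric
#' precision (so write-then-read round-trips exactly).
#'
#' @param samples A sample tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Read an element parameter CSV
#'
#' Columns: `element`, `rfd_mg_per_kg_d`, optional `csf_per_mg_per_kg_d`,
#' `loq`, `loq_unit`.
#'
#' @param path CSV file path.
#' @return A validated element parameter tibble (see [element_params()]).
#' @export
read_element_params <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("element", "rfd_mg_per_kg_d") %in% names(raw))) {
    stop("element file needs columns 'element' and 'rfd_mg_per_kg_d'",
         call. = FALSE)
  }
  params <- tibble::tibble(
    element = normalize_element(raw$element),
    rfd = as.numeric(raw$rfd_mg_per_kg_d),
    csf = if ("csf_per_mg_per_kg_d" %in% names(raw))
      as.numeric(raw$csf_per_mg_per_kg_d) else NA_real_,
    loq = if ("loq" %in% names(raw)) as.numeric(raw$loq) else NA_real_,
    loq_unit = if ("loq_unit" %in% names(raw))
      as.character(raw$loq_unit) else NA_character_
  )
  validate_element_params(params)
}

#' Read an exposure configuration file
#'
#' YAML-style key-value file with any of the [exposure_model()] fields
#' (`fir`, `bw`, `ef`, `ed`, `at_noncarc`, `at_carc`); unspecified
#' fields keep their defaults.
#'
#' @param path File path.
#' @return An [exposure_model()].
#' @export
read_exposure <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c("fir", "bw", "ef", "ed", "at_noncarc", "at_carc")
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("unknown exposure key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(exposure_model, lapply(vals, as.numeric))
}

#' Run the full analysis chain
#'
#' Binds the pipeline stages into the end-to-end analysis: per-element
#' variety comparison of the measured concentrations (ANOVA with letter
#' display), bioaccessibility per variety, and per-element and
#' per-variety risk (EDI, THQ, TTHQ, ILCR, percent-of-reference).
#' Letter displays are only computed where every variety carries
#' replicated measurements.
#'
#' @param samples Long sample tibble (or a path to a sample CSV).
#' @param params Element parameter table.
#' @param model An [exposure_model()].
#' @param route Digestible-concentration route for bioaccessibility:
#'   `"measured"` or `"subtraction"`.
#' @param risk_preparation Preparation whose concentrations enter the
#'   risk equations.
#' @param alpha Significance level for the letter displays.
#' @param out_dir Optional directory: each table is also written as a
#'   CSV (numbers serialized with full precision).
#' @return A named list of tibbles: `concentration_summary`,
#'   `bioaccessibility`, `risk_per_element`, `risk_per_variety`.
#' @export
#' @examples
#' study <- generate_study(simulation_config(n_varieties = 4), seed = 1)
#' res <- run_full_analysis(study$samples)
#' res$risk_per_variety
run_full_analysis <- function(samples, params = element_params(),
                              model = exposure_model(),
                              route = c("measured", "subtraction"),
                              risk_preparation = "digestible",
                              alpha = 0.05, out_dir = NULL) {
  route <- match.arg(route)
  if (is.character(samples) && length(samples) == 1) {
    samples <- read_samples(samples)
  }
  samples <- validate_samples(samples)
  if (nrow(samples) == 0) stop("empty sample table", call. = FALSE)
  params <- validate_element_params(params)

  # per-element, per-preparation variety comparison with letters where
  # the design is replicated
  concentration_summary <- samples |>
    dplyr::mutate(value = as_mg_per_g(.data$value, .data$unit)) |>
    dplyr::group_by(.data$preparation, .data$element) |>
    dplyr::group_modify(function(d, key) {
      groups <- split(d$value, d$variety)
      if (length(groups) >= 2 && all(lengths(groups) >= 2) &&
          stats::var(d$value) > 0) {
        cmp <- group_compare(groups, alpha = alpha)
        out <- cmp$summary
        out$f_stat <- cmp$anova$f_stat
        out$p_value <- cmp$anova$p_value
      } else {
        out <- tibble::tibble(
          group = names(groups),
          n = lengths(groups),
          mean = vapply(groups, mean, numeric(1)),
          sd = vapply(groups, stats::sd, numeric(1)),
          letters = NA_character_, f_stat = NA_real_, p_value = NA_real_)
      }
      dplyr::rename(out, variety = "group")
    }) |>
    dplyr::ungroup()

  bio <- NULL
  need <- if (route == "measured") "digestible" else "non_digestible"
  if (all(c("cooked", need) %in% samples$preparation)) {
    bio <- bioaccessibility_table(samples, route = route)
  }

  risk <- assess_risk(samples, params = params, model = model,
                      preparation = risk_preparation)

  tables <- list(
    concentration_summary = concentration_summary,
    bioaccessibility = bio,
    risk_per_element = risk$per_element,
    risk_per_variety = risk$per_variety
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      utils::write.csv(as.data.frame(tables[[nm]]),
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  tables
}
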