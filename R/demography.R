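#' Build a contraceptive survey series
#'
#' A survey series holds one row per survey round (year, women of reproductive
#' age, percentage of WRA in union) together with a long prevalence table
#' (year, method, prevalence among in-union WRA). It is the input to the
#' demographic projection stage.
#'
#' @param demography Data frame with columns `year`, `wra`, `pct_in_union`
#'   (`wra` and `pct_in_union` may be `NA` for rounds that did not measure
#'   them). Years must be unique and are sorted increasing.
#' @param prevalence Data frame with columns `year`, `method`,
#'   `prevalence_pct`; every year must appear in `demography` and every year
#'   must carry the same method set.
#' @return An object of class `fp_survey_series`: a list with tibbles
#'   `demography` and `prevalence`.
#' @seealso [read_survey_series()], [project_prevalence()]
#' @export
survey_series <- function(demography, prevalence) {
  demography <- tibble::as_tibble(demography)
  prevalence <- tibble::as_tibble(prevalence)
  stopifnot(all(c("year", "wra", "pct_in_union") %in% names(demography)),
            all(c("year", "method", "prevalence_pct") %in% names(prevalence)))
  if (nrow(demography) < 1L) {
    fp_abort("a survey series needs at least one survey round", "fp_insufficient_data")
  }
  if (anyDuplicated(demography$year)) {
    fp_abort("survey years must be unique", "fp_invalid_input")
  }
  if (any(demography$year < 1900)) {
    fp_abort("survey years before 1900 are not supported", "fp_invalid_input")
  }
  bad_pct <- stats::na.omit(demography$pct_in_union)
  if (any(bad_pct < 0 | bad_pct > 100)) {
    fp_abort("pct_in_union must lie in [0, 100]", "fp_invalid_input")
  }
  if (any(prevalence$prevalence_pct < 0 | prevalence$prevalence_pct > 100)) {
    fp_abort("prevalences must lie in [0, 100]", "fp_invalid_input")
  }
  if (!all(prevalence$year %in% demography$year)) {
    fp_abort("prevalence rows refer to years absent from the demography table",
             "fp_invalid_input")
  }
  # every round must carry the same method vocabulary
  methods_by_year <- split(prevalence$method, prevalence$year)
  if (length(methods_by_year) > 0L) {
    ref <- sort(methods_by_year[[1L]])
    same <- vapply(methods_by_year, function(m) identical(sort(m), ref), logical(1))
    if (!all(same)) {
      fp_abort("all survey rounds must report the same method set", "fp_invalid_input")
    }
    sums <- tapply(prevalence$prevalence_pct, prevalence$year, sum)
    if (any(sums > 100 + 1e-9)) {
      fp_abort("method prevalences in a round must sum to at most 100", "fp_invalid_input")
    }
  }
  demography <- dplyr::arrange(demography, .data$year)
  prevalence <- dplyr::arrange(prevalence, .data$year, .data$method)
  structure(list(demography = demography, prevalence = prevalence),
            class = "fp_survey_series")
}

#' @export
print.fp_survey_series <- function(x, ...) {
  cat("<fp_survey_series> ", nrow(x$demography), " round(s): ",
      paste(x$demography$year, collapse = ", "), "\n", sep = "")
  cat("methods: ", paste(unique(x$prevalence$method), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Methods carried by a survey series
#' @param series An `fp_survey_series`.
#' @return Character vector of method names.
#' @export
series_methods <- function(series) {
  unique(series$prevalence$method)
}

#' Read a survey series from CSV
#'
#' Long format, one row per (survey year, method):
#' `year, wra, pct_in_union, method, prevalence_pct`. The per-year demographic
#' columns must be constant within a year; they are collapsed to one row per
#' round.
#'
#' @param path CSV file path.
#' @return An `fp_survey_series`.
#' @export
read_survey_series <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    wra = readr::col_double(),
    pct_in_union = readr::col_double(),
    method = readr::col_character(),
    prevalence_pct = readr::col_double()
  ))
  demography <- dplyr::distinct(raw, .data$year, .data$wra, .data$pct_in_union)
  if (anyDuplicated(demography$year)) {
    fp_abort("wra / pct_in_union differ within a survey year", "fp_invalid_input")
  }
  survey_series(demography, raw[, c("year", "method", "prevalence_pct")])
}

#' Write a survey series to CSV (inverse of [read_survey_series()])
#' @param series An `fp_survey_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_series <- function(series, path) {
  long <- dplyr::left_join(series$prevalence, series$demography, by = "year")
  readr::write_csv(long[, c("year", "wra", "pct_in_union", "method", "prevalence_pct")],
                   path)
  invisible(path)
}

#' Geometric population projection
#'
#' Compounds an annual growth rate over a number of periods:
#' `base_count * (1 + growth_rate_pct/100)^periods`. No rounding is applied;
#' rounding is a reporting concern.
#'
#' @param base_count Population at the base year (non-negative).
#' @param growth_rate_pct Annual rate of population increase, percent per year
#'   (must exceed -100).
#' @param periods Number of years to project over (non-negative, fractional
#'   allowed).
#' @return Projected count (fractional).
#' @examples
#' project_population(100, 10, 2)  # 121
#' @export
project_population <- function(base_count, growth_rate_pct, periods) {
  if (any(base_count < 0)) fp_abort("base_count must be non-negative", "fp_domain_error")
  if (any(periods < 0)) fp_abort("periods must be non-negative", "fp_domain_error")
  if (any(growth_rate_pct <= -100)) {
    fp_abort("growth_rate_pct must exceed -100", "fp_domain_error")
  }
  base_count * (1 + growth_rate_pct / 100)^periods
}

#' Women of reproductive age in union
#'
#' `wra * pct_in_union / 100`, kept at full precision; round half-up only when
#' reporting.
#'
#' @param wra Count of women of reproductive age.
#' @param pct_in_union Percentage in union, in `[0, 100]`.
#' @return In-union count (fractional).
#' @export
project_in_union <- function(wra, pct_in_union) {
  if (any(pct_in_union < 0 | pct_in_union > 100)) {
    fp_abort("pct_in_union must lie in [0, 100]", "fp_domain_error")
  }
  wra * pct_in_union / 100
}

#' Project method prevalence to a target year
#'
#' Linear trend projection of a method's prevalence among in-union WRA.
#' `"two-point"` draws the line through the two survey rounds bracketing the
#' target year (the last two rounds when extrapolating forward, the first two
#' when extrapolating backward); `"least-squares"` fits an ordinary linear
#' trend over all rounds. Results are clamped to `[0, 100]`.
#'
#' @param series An `fp_survey_series`.
#' @param method Method name present in the series.
#' @param target_year Year to project to.
#' @param mode `"two-point"` (default) or `"least-squares"`.
#' @return Projected prevalence percentage.
#' @export
project_prevalence <- function(series, method, target_year,
                               mode = c("two-point", "least-squares")) {
  mode <- match.arg(mode)
  if (!method %in% series$prevalence$method) {
    fp_abort(paste0("unknown method: ", method), "fp_key_error")
  }
  pts <- dplyr::filter(series$prevalence, .data$method == !!method)
  pts <- dplyr::arrange(pts, .data$year)
  if (target_year %in% pts$year && nrow(pts) >= 1L) {
    # identity at a survey year, regardless of mode or point count
    if (mode == "two-point" || nrow(pts) < 2L) {
      return(pts$prevalence_pct[pts$year == target_year])
    }
  }
  if (nrow(pts) < 2L) {
    fp_abort("at least two survey rounds are needed to project a prevalence",
             "fp_insufficient_data")
  }
  if (mode == "two-point") {
    below <- which(pts$year <= target_year)
    above <- which(pts$year >= target_year)
    if (length(below) == 0L) {
      pair <- pts[1:2, ]                      # backward extrapolation
    } else if (length(above) == 0L) {
      pair <- pts[(nrow(pts) - 1L):nrow(pts), ] # forward extrapolation
    } else {
      pair <- pts[c(max(below), min(above)), ]
      if (pair$year[1] == pair$year[2]) pair <- pts[c(max(below) - 1L, max(below)), ]
    }
    slope <- (pair$prevalence_pct[2] - pair$prevalence_pct[1]) /
      (pair$year[2] - pair$year[1])
    value <- pair$prevalence_pct[1] + slope * (target_year - pair$year[1])
  } else {
    fit <- stats::lm(prevalence_pct ~ year, data = pts)
    value <- unname(stats::predict(fit, newdata = data.frame(year = target_year)))
  }
  min(100, max(0, value))
}

#' Contraceptive users for one method
#'
#' @param wra_in_union Count of in-union women of reproductive age.
#' @param prevalence_pct Method prevalence percentage, in `[0, 100]`.
#' @return `wra_in_union * prevalence_pct / 100` (fractional; rounding is a
#'   reporting concern).
#' @export
users_by_method <- function(wra_in_union, prevalence_pct) {
  if (any(wra_in_union < 0)) fp_abort("wra_in_union must be non-negative", "fp_domain_error")
  if (any(prevalence_pct < 0 | prevalence_pct > 100)) {
    fp_abort("prevalence_pct must lie in [0, 100]", "fp_domain_error")
  }
  wra_in_union * prevalence_pct / 100
}

#' Full demographic projection to a target year
#'
#' Carries out the population-and-prevalence stage of the pipeline: projects
#' WRA with the geometric growth model (or accepts a published projected value
#' as an override), holds the percentage in union at the most recent survey's
#' value, projects each method's prevalence, and derives in-union WRA, users
#' and the modern contraceptive prevalence rate (mCPR, the sum of the modern
#' per-method prevalences).
#'
#' @param series An `fp_survey_series`.
#' @param target_year Year to project to.
#' @param growth_rate_pct Annual population growth rate (%). Defaults to the
#'   rate implied by the last two survey rounds with a `wra` value.
#' @param mode Prevalence projection mode, see [project_prevalence()].
#' @param overrides Optional list pinning published projected values instead of
#'   recomputing them: `wra` (projected WRA count) and/or `prevalence` (named
#'   numeric, method -> percentage). Published national tables often print
#'   projections whose exact interpolation convention is not stated; overrides
#'   let a scenario reproduce such tables verbatim while the model path stays
#'   the default.
#' @return An object of class `fp_projection`: list with `target_year`, `wra`,
#'   `growth_rate_pct`, `pct_in_union`, `wra_in_union`, `prevalence` (named
#'   numeric), `users` (named numeric) and `mcpr`.
#' @export
project_demography <- function(series, target_year, growth_rate_pct = NULL,
                               mode = c("two-point", "least-squares"),
                               overrides = NULL) {
  mode <- match.arg(mode)
  demo <- dplyr::filter(series$demography, !is.na(.data$wra))
  if (nrow(demo) == 0L) fp_abort("no survey round carries a WRA count", "fp_insufficient_data")
  last <- demo[nrow(demo), ]

  if (is.null(growth_rate_pct)) {
    if (nrow(demo) >= 2L) {
      prev <- demo[nrow(demo) - 1L, ]
      growth_rate_pct <-
        100 * ((last$wra / prev$wra)^(1 / (last$year - prev$year)) - 1)
    } else {
      growth_rate_pct <- 0
    }
  }

  wra <- overrides$wra %||%
    project_population(last$wra, growth_rate_pct, target_year - last$year)

  in_union_obs <- dplyr::filter(series$demography, !is.na(.data$pct_in_union))
  if (nrow(in_union_obs) == 0L) {
    fp_abort("no survey round carries pct_in_union", "fp_insufficient_data")
  }
  pct_in_union <- in_union_obs$pct_in_union[nrow(in_union_obs)]
  wra_in_union <- project_in_union(wra, pct_in_union)

  methods <- series_methods(series)
  prevalence <- vapply(methods, function(m) {
    ov <- overrides$prevalence
    if (!is.null(ov) && m %in% names(ov)) return(unname(ov[[m]]))
    project_prevalence(series, m, target_year, mode = mode)
  }, numeric(1))

  structure(list(
    target_year = target_year,
    wra = wra,
    growth_rate_pct = growth_rate_pct,
    pct_in_union = pct_in_union,
    wra_in_union = wra_in_union,
    prevalence = prevalence,
    users = users_by_method(wra_in_union, prevalence),
    mcpr = sum(prevalence)
  ), class = "fp_projection")
}

#' @export
print.fp_projection <- function(x, ...) {
  cat("<fp_projection> target year ", x$target_year, "\n", sep = "")
  cat("  WRA: ", format_amount(round_half_up(x$wra)),
      "  in union (", formatC(x$pct_in_union, format = "f", digits = 2), "%): ",
      format_amount(round_half_up(x$wra_in_union)), "\n", sep = "")
  cat("  mCPR: ", round_half_up(x$mcpr, 1), "%\n", sep = "")
  invisible(x)
}

#' Serialize a projection as JSON
#'
#' Mirrors the layout of a published contraceptive-needs projection table:
#' WRA, growth rate, percent/number in union, per-method prevalence and mCPR.
#' Counts are rounded half-up to integers and percentages to one decimal, as
#' such tables print them.
#'
#' @param projection An `fp_projection`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
projection_json <- function(projection, path = NULL) {
  out <- list(
    target_year = projection$target_year,
    wra = round_half_up(projection$wra, 1),
    annual_rate_of_population_increase_pct = round_half_up(projection$growth_rate_pct, 2),
    pct_wra_in_union = round_half_up(projection$pct_in_union, 2),
    wra_in_union = round_half_up(projection$wra_in_union),
    prevalence_by_method_pct = as.list(round_half_up(projection$prevalence, 1)),
    mcpr_pct = round_half_up(projection$mcpr, 1)
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
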