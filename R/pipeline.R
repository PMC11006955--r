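#' Bundle the three pipeline inputs into a scenario
#'
#' A scenario is one self-contained analysis: a survey series, a method-profile
#' table, a fund-flow ledger and a config. The config is a plain list with
#' entries `target_year` (required), `growth_rate_pct`, `prevalence_mode`
#' (`"two-point"` or `"least-squares"`), `currency`,
#' `exchange_rate_idr_per_usd`, `overrides` (see [project_demography()]) and
#' `groups` (named institution groups for [fund_indicators()]).
#'
#' @param survey_series An `fp_survey_series`.
#' @param profiles An `fp_method_profiles` covering the series' methods.
#' @param ledger An `fp_flow_edges`.
#' @param config Config list; `target_year` is required.
#' @return An `fp_scenario`.
#' @export
scenario <- function(survey_series, profiles, ledger, config) {
  stopifnot(inherits(survey_series, "fp_survey_series"))
  profiles <- if (inherits(profiles, "fp_method_profiles")) profiles else method_profiles(profiles)
  ledger <- if (inherits(ledger, "fp_flow_edges")) ledger else flow_edges(ledger)
  if (is.null(config$target_year)) {
    fp_abort("config must set target_year", "fp_config_error")
  }
  uncovered <- setdiff(series_methods(survey_series), profiles$method)
  if (length(uncovered)) {
    fp_abort(paste("survey methods without a profile:",
                   paste(uncovered, collapse = ", ")), "fp_config_error")
  }
  unknown <- setdiff(unlist(config$groups), unique(ledger$institution))
  if (length(unknown)) {
    fp_abort(paste("group institutions absent from ledger:",
                   paste(unknown, collapse = ", ")), "fp_config_error")
  }
  structure(list(survey_series = survey_series, profiles = profiles,
                 ledger = ledger, config = config),
            class = "fp_scenario")
}

#' Read a scenario from a directory
#'
#' Expects `survey_series.csv`, a method-profile CSV (`method_profiles.csv` or
#' `method_profiles_synthetic.csv`), `ledger.csv` and `config.yaml` in `dir`,
#' in the package's standard formats.
#'
#' @param dir Directory path.
#' @return An `fp_scenario`.
#' @export
read_scenario <- function(dir) {
  profile_file <- file.path(dir, "method_profiles.csv")
  if (!file.exists(profile_file)) {
    profile_file <- file.path(dir, "method_profiles_synthetic.csv")
  }
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  if (!is.null(config$overrides$prevalence)) {
    config$overrides$prevalence <- unlist(config$overrides$prevalence)
  }
  scenario(
    survey_series = read_survey_series(file.path(dir, "survey_series.csv")),
    profiles = read_method_profiles(profile_file),
    ledger = read_ledger(file.path(dir, "ledger.csv")),
    config = config
  )
}

#' Write a scenario to a directory (inverse of [read_scenario()])
#' @param x An `fp_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_survey_series(x$survey_series, file.path(dir, "survey_series.csv"))
  write_method_profiles(x$profiles, file.path(dir, "method_profiles.csv"))
  write_ledger(x$ledger, file.path(dir, "ledger.csv"))
  cfg <- x$config
  if (!is.null(cfg$overrides$prevalence)) {
    cfg$overrides$prevalence <- as.list(cfg$overrides$prevalence)
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Run the full fund-flow pipeline on a scenario
#'
#' Executes the stages in order — demographic projection, CYP costing,
#' fund-flow matrix, column shares, indicators, conservation check — and
#' returns everything in one report. Deterministic: identical scenarios give
#' identical reports, and the report records a hash of its inputs as
#' provenance.
#'
#' @param scenario An `fp_scenario`.
#' @return An `fp_run_report`: list with `projection`, `spending`, `matrix`,
#'   `shares`, `indicators`, `violations`, `provenance`.
#' @export
run_pipeline <- function(scenario) {
  stopifnot(inherits(scenario, "fp_scenario"))
  cfg <- scenario$config
  projection <- project_demography(
    scenario$survey_series,
    target_year = cfg$target_year,
    growth_rate_pct = cfg$growth_rate_pct,
    mode = cfg$prevalence_mode %||% "two-point",
    overrides = cfg$overrides
  )
  spending <- build_spending_table(projection, scenario$profiles)
  matrix <- build_matrix(scenario$ledger)
  shares <- column_shares(matrix)
  indicators <- fund_indicators(matrix, cfg$groups %||% list())
  violations <- validate_conservation(matrix, scenario$ledger)
  structure(list(
    projection = projection,
    spending = spending,
    matrix = matrix,
    shares = shares,
    indicators = indicators,
    violations = violations,
    provenance = list(
      input_hash = rlang::hash(scenario),
      package_version = as.character(utils::packageVersion("fpfundflow"))
    )
  ), class = "fp_run_report")
}

#' @export
print.fp_run_report <- function(x, ...) {
  cat("<fp_run_report>\n")
  print(x$projection)
  cat("  origin column total: ",
      format_amount(x$matrix$column_totals[["NATIONAL"]]), "\n", sep = "")
  cat("  indicators:\n")
  print(x$indicators)
  cat("  conservation violations: ", nrow(x$violations), "\n", sep = "")
  invisible(x)
}

stage_display_names <- c(
  NATIONAL = "National Budget/ Original Source [%]",
  PROVINCIAL = "Provincial-Level Budget [%]",
  DISTRICT = "District-Level Budget [%]",
  EXPENDITURE_PUBLIC = "Estimated Expenditure for Public Sector [%]",
  EXPENDITURE_PRIVATE = "Estimated Expenditure for Private Sector [%]",
  LEAKAGE = "Leakage [%]"
)

#' Render the fund-flow matrix as a Markdown table
#'
#' Mirrors the published layout: one row per institution, each cell
#' `"<amount> [<share>%]"` with thousands separators and two-decimal shares,
#' `"-"` for absent cells and a closing `Total` row at `[100.00%]` per column.
#' Stage columns with no flows at all are dropped.
#'
#' @param matrix An `fp_fundflow_matrix`.
#' @param shares The matching `fp_share_matrix`.
#' @return A single Markdown string.
#' @export
render_matrix_markdown <- function(matrix, shares) {
  stages <- shares$stages
  header <- c("Institution(s)", unname(stage_display_names[stages]))
  fmt_cell <- function(amount, share) {
    if (is.na(amount)) return("-")
    paste0(format_amount(amount), " [",
           formatC(share, format = "f", digits = 2), "%]")
  }
  body <- vapply(matrix$institutions, function(inst) {
    cells <- vapply(stages, function(s) {
      fmt_cell(matrix$amounts[inst, s], shares$shares[inst, s])
    }, character(1))
    paste(c(inst, cells), collapse = " | ")
  }, character(1))
  total_row <- paste(
    c("Total", vapply(stages, function(s) {
      paste0(format_amount(matrix$column_totals[[s]]), " [100.00%]")
    }, character(1))),
    collapse = " | ")
  paste(c(
    paste(header, collapse = " | "),
    paste(rep("---", length(header)), collapse = " | "),
    body, total_row
  ), collapse = "\n")
}

#' Write / read the fund-flow matrix as CSV
#'
#' Long format `institution, stage, amount`; absent cells are written with an
#' empty amount and round-trip back to absent.
#'
#' @param matrix An `fp_fundflow_matrix`.
#' @param path CSV path.
#' @return `write_matrix_csv()` returns `path` invisibly; `read_matrix_csv()`
#'   an `fp_fundflow_matrix`.
#' @export
write_matrix_csv <- function(matrix, path) {
  long <- tidyr::expand_grid(institution = matrix$institutions,
                             stage = matrix$stages) |>
    dplyr::mutate(amount = purrr::map2_dbl(
      .data$institution, .data$stage, ~ matrix$amounts[.x, .y]))
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    institution = readr::col_character(),
    stage = readr::col_character(),
    amount = readr::col_double()
  ))
  institutions <- unique(long$institution)
  stages <- setdiff(fp_stages(), "ORIGIN")
  amounts <- matrix(NA_real_, length(institutions), length(stages),
                    dimnames = list(institutions, stages))
  for (i in seq_len(nrow(long))) {
    amounts[long$institution[i], long$stage[i]] <- long$amount[i]
  }
  structure(list(amounts = amounts,
                 column_totals = colSums(amounts, na.rm = TRUE),
                 institutions = institutions, stages = stages),
            class = "fp_fundflow_matrix")
}

report_to_list <- function(report) {
  m <- report$matrix
  cells <- tidyr::expand_grid(institution = m$institutions, stage = m$stages) |>
    dplyr::mutate(
      amount = purrr::map2_dbl(.data$institution, .data$stage,
                               ~ m$amounts[.x, .y]),
      share_pct = purrr::map2_dbl(.data$institution, .data$stage,
                                  ~ report$shares$shares[.x, .y])
    )
  list(
    projection = list(
      target_year = report$projection$target_year,
      wra = report$projection$wra,
      growth_rate_pct = report$projection$growth_rate_pct,
      pct_in_union = report$projection$pct_in_union,
      wra_in_union = report$projection$wra_in_union,
      prevalence_pct = as.list(report$projection$prevalence),
      mcpr_pct = report$projection$mcpr
    ),
    spending = list(
      rows = tibble::as_tibble(report$spending),
      sector_totals = as.list(spending_totals(report$spending)$sector_totals),
      grand_total = spending_totals(report$spending)$grand_total
    ),
    matrix = list(cells = cells,
                  column_totals = as.list(m$column_totals)),
    indicators = unclass(report$indicators),
    violations = report$violations,
    provenance = report$provenance
  )
}

# structural validation of a rendered report list; the JSON writer runs it
# before serializing, and readers can run it on parsed JSON
validate_report_list <- function(x) {
  required <- c("projection", "spending", "matrix", "indicators",
                "violations", "provenance")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    fp_abort(paste("report lacks sections:", paste(missing, collapse = ", ")),
             "fp_schema_error")
  }
  proj_fields <- c("target_year", "wra", "pct_in_union", "wra_in_union",
                   "prevalence_pct", "mcpr_pct")
  if (length(setdiff(proj_fields, names(x$projection)))) {
    fp_abort("report projection section incomplete", "fp_schema_error")
  }
  if (length(setdiff(c("cells", "column_totals"), names(x$matrix)))) {
    fp_abort("report matrix section incomplete", "fp_schema_error")
  }
  invisible(TRUE)
}

#' Render a run report
#'
#' `"markdown"` produces the published-table layout (see
#' [render_matrix_markdown()]) plus projection and indicator summaries;
#' `"json"` a schema-checked machine-readable document; `"csv"` the matrix in
#' long form (plus the spending table when `path` is a directory).
#'
#' @param report An `fp_run_report`.
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param path Optional output file (for csv: file for the matrix). When
#'   `NULL`, the rendered text is returned.
#' @return Rendered text (markdown/json) or `path`, invisibly when writing.
#' @export
render_report <- function(report, format = c("markdown", "csv", "json"),
                          path = NULL) {
  format <- match.arg(format)
  if (format == "markdown") {
    proj <- report$projection
    ind <- report$indicators
    txt <- paste0(
      "## Demographic projection (", proj$target_year, ")\n\n",
      "WRA: ", format_amount(proj$wra, 1),
      "; in union: ", format_amount(round_half_up(proj$wra_in_union)),
      " (", formatC(proj$pct_in_union, format = "f", digits = 2), "%)",
      "; mCPR: ", round_half_up(proj$mcpr, 1), "%\n\n",
      "## Fund-flow matrix\n\n",
      render_matrix_markdown(report$matrix, report$shares), "\n\n",
      "## Indicators\n\n",
      paste(vapply(names(ind), function(nm) {
        paste0("- ", nm, ": ", formatC(round_half_up(ind[[nm]], 2),
                                       format = "f", digits = 2))
      }, character(1)), collapse = "\n"), "\n")
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    return(invisible(path))
  }
  if (format == "json") {
    lst <- report_to_list(report)
    validate_report_list(lst)
    json <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    if (is.null(path)) return(json)
    writeLines(json, path)
    return(invisible(path))
  }
  # csv
  if (is.null(path)) fp_abort("csv rendering needs a path", "fp_usage_error")
  write_matrix_csv(report$matrix, path)
  invisible(path)
}
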