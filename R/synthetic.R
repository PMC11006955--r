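#' Specification for a synthetic scenario
#'
#' Defines every parameter of a generated study scenario: the survey calendar
#' and demographic baseline, per-method linear prevalence trends, and the
#' shape of the fund-flow ledger. A single seed drives all randomness; each
#' generator component derives its own sub-stream from it, so adding a
#' component never perturbs the output of another.
#'
#' Defaults mirror a national FP financing study at Indonesia's scale: five
#' survey rounds on the DHS calendar (1997--2017) projected to 2019, eight
#' modern-method categories, ~72 million WRA growing at about 1% per year,
#' 71.9% in union, and a ledger in USD thousands whose institutions lose
#' 5--20% of each transfer to leakage and split terminal spending between
#' sectors.
#'
#' @param seed Integer RNG seed.
#' @param n_methods Number of contraceptive methods.
#' @param n_institutions Number of funding institutions.
#' @param base_wra WRA count at the first survey year.
#' @param growth_rate_pct Annual population growth, percent.
#' @param pct_in_union Percentage of WRA in union.
#' @param survey_years Strictly increasing survey calendar.
#' @param target_year Projection target year.
#' @param prevalence_trends Optional tibble `method, intercept, slope`
#'   (percentage at the first survey year and change per year); generated
#'   from the seed when `NULL`.
#' @param noise_halfwidth_pct Half-width of the bounded uniform noise added to
#'   each observed prevalence, percentage points. `0` gives exactly linear
#'   series.
#' @param leakage_fraction_range Interval in `[0, 1)` from which each transit
#'   stage's leakage fraction is drawn.
#' @param sector_split_range Interval from which the public share of terminal
#'   spending is drawn.
#' @param currency Ledger currency code.
#' @return A list of class `fp_scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L,
                          n_methods = 8L,
                          n_institutions = 6L,
                          base_wra = 6.2e7,
                          growth_rate_pct = 1.06,
                          pct_in_union = 71.9,
                          survey_years = c(1997L, 2002L, 2007L, 2012L, 2017L),
                          target_year = 2019L,
                          prevalence_trends = NULL,
                          noise_halfwidth_pct = 0.5,
                          leakage_fraction_range = c(0.05, 0.20),
                          sector_split_range = c(0.30, 0.70),
                          currency = "USD") {
  if (length(survey_years) == 0L) {
    fp_abort("survey_years must not be empty", "fp_config_error")
  }
  if (is.unsorted(survey_years, strictly = TRUE)) {
    fp_abort("survey_years must be strictly increasing", "fp_config_error")
  }
  stopifnot(noise_halfwidth_pct >= 0,
            leakage_fraction_range[1] >= 0, leakage_fraction_range[2] < 1,
            leakage_fraction_range[1] <= leakage_fraction_range[2],
            sector_split_range[1] >= 0, sector_split_range[2] <= 1)
  spec <- list(seed = as.integer(seed), n_methods = as.integer(n_methods),
               n_institutions = as.integer(n_institutions),
               base_wra = base_wra, growth_rate_pct = growth_rate_pct,
               pct_in_union = pct_in_union,
               survey_years = as.integer(survey_years),
               target_year = as.integer(target_year),
               prevalence_trends = prevalence_trends,
               noise_halfwidth_pct = noise_halfwidth_pct,
               leakage_fraction_range = leakage_fraction_range,
               sector_split_range = sector_split_range,
               currency = currency)
  if (is.null(spec$prevalence_trends)) {
    spec$prevalence_trends <- generate_trends(spec)
  }
  structure(spec, class = "fp_scenario_spec")
}

# derive a per-component RNG sub-stream seed; offsets are arbitrary fixed
# primes so components never share a stream
substream_seed <- function(seed, component) {
  offsets <- c(trends = 104729L, survey = 224737L, ledger = 350377L,
               profiles = 479909L)
  (as.integer(seed) + offsets[[component]]) %% .Machine$integer.max
}

generate_trends <- function(spec) {
  if (spec$n_methods == 0L) {
    return(tibble::tibble(method = character(), intercept = numeric(),
                          slope = numeric()))
  }
  set.seed(substream_seed(spec$seed, "trends"))
  tibble::tibble(
    method = sprintf("method_%02d", seq_len(spec$n_methods)),
    intercept = stats::runif(spec$n_methods, 1, 6),
    slope = stats::runif(spec$n_methods, -0.10, 0.20)
  )
}

#' Generate a synthetic survey series
#'
#' Prevalences follow the spec's per-method linear trends with bounded uniform
#' noise; WRA follows the geometric growth model; the in-union percentage is
#' constant. Deterministic for a fixed seed.
#'
#' @param spec An `fp_scenario_spec`.
#' @return An `fp_survey_series`.
#' @export
generate_survey_series <- function(spec) {
  years <- spec$survey_years
  set.seed(substream_seed(spec$seed, "survey"))
  demography <- tibble::tibble(
    year = years,
    wra = project_population(spec$base_wra, spec$growth_rate_pct, years - years[1]),
    pct_in_union = spec$pct_in_union
  )
  trends <- spec$prevalence_trends
  if (nrow(trends) == 0L) {
    prevalence <- tibble::tibble(year = integer(), method = character(),
                                 prevalence_pct = numeric())
  } else {
    prevalence <- tidyr::crossing(year = years, method = trends$method) |>
      dplyr::left_join(trends, by = "method") |>
      dplyr::mutate(
        noise = stats::runif(dplyr::n(), -spec$noise_halfwidth_pct,
                             spec$noise_halfwidth_pct),
        prevalence_pct = pmin(100, pmax(
          0, .data$intercept + .data$slope * (.data$year - years[1]) + .data$noise))
      ) |>
      dplyr::select("year", "method", "prevalence_pct")
  }
  survey_series(demography, prevalence)
}

#' Generate synthetic method profiles
#'
#' One profile per trend method; kinds, CYP factors, unit costs and sector
#' splits drawn from ranges typical of contraceptive costing tables.
#'
#' @param spec An `fp_scenario_spec`.
#' @return An `fp_method_profiles`.
#' @export
generate_method_profiles <- function(spec) {
  n <- spec$n_methods
  if (n == 0L) {
    return(method_profiles(tibble::tibble(
      method = character(), kind = character(), units_per_cyp = numeric(),
      cyp_per_procedure = numeric(), unit_cost_public = numeric(),
      unit_cost_private = numeric(), source_public_pct = numeric(),
      source_private_pct = numeric(), currency = character())))
  }
  set.seed(substream_seed(spec$seed, "profiles"))
  kind <- sample(c("resupply", "long-acting", "permanent"), n, replace = TRUE)
  pub <- stats::runif(n, 20, 80)
  method_profiles(tibble::tibble(
    method = spec$prevalence_trends$method,
    kind = kind,
    units_per_cyp = ifelse(kind == "resupply", stats::runif(n, 2, 150), NA),
    cyp_per_procedure = ifelse(kind == "resupply", NA, stats::runif(n, 1.5, 13)),
    unit_cost_public = stats::runif(n, 0.5, 30),
    unit_cost_private = stats::runif(n, 0.5, 60),
    source_public_pct = pub,
    source_private_pct = 100 - pub,
    currency = spec$currency
  ))
}

#' Generate a conservative fund-flow ledger with known ground truth
#'
#' Every institution receives an origin amount at the NATIONAL stage, passes
#' through a random subset of the lower transit stages, loses a drawn leakage
#' fraction at each transit stage (recorded as an explicit LEAKAGE edge), and
#' splits the remainder between public and private expenditure. Conservation
#' therefore holds exactly by construction. Alongside the edges, the
#' generator's own running arithmetic (independent of the matrix-building
#' code) records the induced column totals, origin shares and sector-share
#' indicators.
#'
#' @param spec An `fp_scenario_spec`.
#' @return List with `edges` (an `fp_flow_edges`) and `ground_truth` (list
#'   with `column_totals`, `origin_shares_pct`, `public_expenditure_share_pct`,
#'   `private_expenditure_share_pct`, `leakage_total`).
#' @export
generate_ledger <- function(spec) {
  set.seed(substream_seed(spec$seed, "ledger"))
  institutions <- sprintf("institution_%02d", seq_len(spec$n_institutions))
  totals <- c(NATIONAL = 0, PROVINCIAL = 0, DISTRICT = 0,
              EXPENDITURE_PUBLIC = 0, EXPENDITURE_PRIVATE = 0, LEAKAGE = 0)
  origin_amounts <- stats::setNames(numeric(length(institutions)), institutions)
  rows <- list()
  add_edge <- function(inst, from, to, amount) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      institution = inst, from_stage = from, to_stage = to, amount = amount,
      currency = spec$currency, note = NA_character_, external = FALSE)
    totals[[to]] <<- totals[[to]] + amount
  }
  for (inst in institutions) {
    origin <- stats::runif(1, 1e3, 3e5)
    origin_amounts[inst] <- origin
    add_edge(inst, "ORIGIN", "NATIONAL", origin)
    path <- c("NATIONAL",
              if (stats::runif(1) < 0.5) "PROVINCIAL",
              if (stats::runif(1) < 0.7) "DISTRICT")
    held <- origin
    for (i in seq_along(path)) {
      leak <- held * stats::runif(1, spec$leakage_fraction_range[1],
                                  spec$leakage_fraction_range[2])
      if (leak > 0) add_edge(inst, path[i], "LEAKAGE", leak)
      held <- held - leak
      if (i < length(path)) {
        add_edge(inst, path[i], path[i + 1L], held)
      }
    }
    p_pub <- stats::runif(1, spec$sector_split_range[1], spec$sector_split_range[2])
    add_edge(inst, path[length(path)], "EXPENDITURE_PUBLIC", held * p_pub)
    add_edge(inst, path[length(path)], "EXPENDITURE_PRIVATE", held * (1 - p_pub))
  }
  origin_total <- sum(origin_amounts)
  ground_truth <- list(
    column_totals = totals,
    origin_shares_pct = 100 * origin_amounts / origin_total,
    public_expenditure_share_pct = 100 * totals[["EXPENDITURE_PUBLIC"]] / origin_total,
    private_expenditure_share_pct = 100 * totals[["EXPENDITURE_PRIVATE"]] / origin_total,
    leakage_total = totals[["LEAKAGE"]]
  )
  list(edges = flow_edges(dplyr::bind_rows(rows)), ground_truth = ground_truth)
}

#' Generate a complete synthetic scenario
#'
#' Bundles [generate_survey_series()], [generate_method_profiles()] and
#' [generate_ledger()] into one runnable scenario with a config projecting to
#' the spec's target year.
#'
#' @param spec An `fp_scenario_spec`.
#' @return List with `scenario` (an `fp_scenario`) and `ground_truth`.
#' @export
generate_scenario <- function(spec) {
  series <- generate_survey_series(spec)
  profiles <- generate_method_profiles(spec)
  ledger <- generate_ledger(spec)
  groups <- as.list(stats::setNames(unique(ledger$edges$institution),
                                    unique(ledger$edges$institution)))
  sc <- scenario(
    survey_series = series,
    profiles = profiles,
    ledger = ledger$edges,
    config = list(target_year = spec$target_year,
                  growth_rate_pct = spec$growth_rate_pct,
                  prevalence_mode = "two-point",
                  currency = spec$currency,
                  groups = groups)
  )
  list(scenario = sc, ground_truth = ledger$ground_truth)
}

#' The published Indonesia-2019 scenario
#'
#' Loads the fixture shipped with the package: the 2017 survey round and the
#' printed 2019 projection overrides, the fund-flow ledger transcribed from
#' the published 2019 matrix (USD thousands, preserving which cells are absent
#' versus true zeros), a synthetic method-profile table (the study's unit-cost
#' supplement is not published in machine-readable form), and the institution
#' groups behind the headline indicators.
#'
#' @return An `fp_scenario`.
#' @export
in_paper_fixture <- function() {
  dir <- system.file("extdata", "indonesia_2019", package = "fpfundflow")
  if (dir == "") fp_abort("fixture directory not found; is the package installed?",
                          "fp_config_error")
  read_scenario(dir)
}
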