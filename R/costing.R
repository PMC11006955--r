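#' Method profiles: CYP factors, unit costs and sector splits
#'
#' A method-profile table drives the costing stage. Each row describes one
#' contraceptive method:
#' * `kind` — `"resupply"` (pills, condoms, injectables: recurring supplies),
#'   `"long-acting"` (IUD, implant) or `"permanent"` (sterilization).
#' * `units_per_cyp` — units consumed per couple-year of protection (CYP);
#'   set for resupply methods only.
#' * `cyp_per_procedure` — couple-years credited per insertion/procedure; set
#'   for long-acting and permanent methods only.
#' * `unit_cost_public` / `unit_cost_private` — price per unit (resupply) or
#'   per procedure, in the profile currency.
#' * `source_public_pct` / `source_private_pct` — percentage of the method's
#'   users served in each sector; must sum to 100.
#'
#' @param profiles Data frame with the columns above plus `method` and
#'   (optionally) `currency`.
#' @return A validated tibble of class `fp_method_profiles`.
#' @export
method_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  required <- c("method", "kind", "units_per_cyp", "cyp_per_procedure",
                "unit_cost_public", "unit_cost_private",
                "source_public_pct", "source_private_pct")
  missing <- setdiff(required, names(profiles))
  if (length(missing)) {
    fp_abort(paste("method profile table lacks columns:",
                   paste(missing, collapse = ", ")), "fp_config_error")
  }
  if (!"currency" %in% names(profiles)) profiles$currency <- NA_character_
  if (anyDuplicated(profiles$method)) {
    fp_abort("duplicate method in profile table", "fp_config_error")
  }
  bad_kind <- setdiff(profiles$kind, c("resupply", "long-acting", "permanent"))
  if (length(bad_kind)) {
    fp_abort(paste("unknown profile kind:", paste(bad_kind, collapse = ", ")),
             "fp_config_error")
  }
  for (i in seq_len(nrow(profiles))) validate_profile_row(profiles[i, ])
  class(profiles) <- c("fp_method_profiles", class(profiles))
  profiles
}

validate_profile_row <- function(row) {
  is_resupply <- row$kind == "resupply"
  if (is_resupply && (is.na(row$units_per_cyp) || !is.na(row$cyp_per_procedure))) {
    fp_abort(paste0("resupply method '", row$method,
                    "' must set units_per_cyp and not cyp_per_procedure"),
             "fp_config_error")
  }
  if (!is_resupply && (is.na(row$cyp_per_procedure) || !is.na(row$units_per_cyp))) {
    fp_abort(paste0("procedure method '", row$method,
                    "' must set cyp_per_procedure and not units_per_cyp"),
             "fp_config_error")
  }
  if (is_resupply && row$units_per_cyp <= 0) {
    fp_abort("units_per_cyp must be positive", "fp_config_error")
  }
  if (!is_resupply && row$cyp_per_procedure <= 0) {
    fp_abort("cyp_per_procedure must be positive", "fp_config_error")
  }
  if (row$unit_cost_public < 0 || row$unit_cost_private < 0) {
    fp_abort("unit costs must be non-negative", "fp_config_error")
  }
  if (abs(row$source_public_pct + row$source_private_pct - 100) > 0.01) {
    fp_abort(paste0("sector source split for '", row$method,
                    "' must sum to 100"), "fp_config_error")
  }
  invisible(row)
}

#' Read / write a method-profile CSV
#'
#' Columns: `method, kind, units_per_cyp, cyp_per_procedure, unit_cost_public,
#' unit_cost_private, source_public_pct, source_private_pct, currency`. Empty
#' cells in the two CYP columns mean "not applicable for this kind".
#'
#' @param path CSV file path.
#' @return `read_method_profiles()`: an `fp_method_profiles` tibble.
#' @export
read_method_profiles <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    method = readr::col_character(),
    kind = readr::col_character(),
    units_per_cyp = readr::col_double(),
    cyp_per_procedure = readr::col_double(),
    unit_cost_public = readr::col_double(),
    unit_cost_private = readr::col_double(),
    source_public_pct = readr::col_double(),
    source_private_pct = readr::col_double(),
    currency = readr::col_character()
  ))
  method_profiles(raw)
}

#' @rdname read_method_profiles
#' @param profiles An `fp_method_profiles` tibble.
#' @export
write_method_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' Reference method profiles (USAID-convention CYP factors)
#'
#' A starting profile table for the eight standard modern-method categories.
#' CYP conversion factors follow the USAID convention (15 pill cycles, 120
#' condoms or 4 three-month injections per CYP; 4.6 CYP per IUD insertion,
#' 2.5 per implant, 10 per sterilization). The unit costs and sector splits
#' are synthetic placeholders — every real analysis must replace them with the
#' country's reimbursement tariffs and service-distribution survey, which are
#' scenario inputs, not constants of the method.
#'
#' @param currency Currency code recorded on the rows (default `"IDR"`).
#' @return An `fp_method_profiles` tibble with eight rows.
#' @export
default_method_profiles <- function(currency = "IDR") {
  method_profiles(tibble::tribble(
    ~method,                ~kind,         ~units_per_cyp, ~cyp_per_procedure, ~unit_cost_public, ~unit_cost_private, ~source_public_pct, ~source_private_pct,
    "tubal ligation",       "permanent",   NA,             10,                 2500000,           4000000,            90,                 10,
    "pills",                "resupply",    15,             NA,                 5000,              15000,              30,                 70,
    "IUD",                  "long-acting", NA,             4.6,                100000,            500000,             45,                 55,
    "injectable",           "resupply",    4,              NA,                 20000,             35000,              25,                 75,
    "condoms",              "resupply",    120,            NA,                 1500,              3000,               30,                 70,
    "implant",              "long-acting", NA,             2.5,                150000,            600000,             55,                 45,
    "male sterilization",   "permanent",   NA,             10,                 2000000,           3500000,            95,                 5,
    "other modern methods", "resupply",    1,              NA,                 50000,             100000,             50,                 50
  ) |> dplyr::mutate(currency = currency))
}

profile_for <- function(profiles, method) {
  row <- profiles[profiles$method == method, ]
  if (nrow(row) != 1L) {
    fp_abort(paste0("no method profile for '", method, "'"), "fp_key_error")
  }
  row
}

#' Annual commodity quantity or procedures for a user stock
#'
#' Resupply methods: each continuing user consumes one CYP's worth of supplies
#' per year, so quantity = `users * units_per_cyp`. Long-acting and permanent
#' methods are costed at steady state: the annual number of
#' insertions/procedures that sustains the user stock is
#' `users / cyp_per_procedure`.
#'
#' @param profile A single-row profile (one row of an `fp_method_profiles`).
#' @param users Current users of the method (non-negative; fractional allowed).
#' @return Annual quantity (units or procedures).
#' @export
annual_quantity <- function(profile, users) {
  if (any(users < 0)) fp_abort("users must be non-negative", "fp_domain_error")
  validate_profile_row(profile)
  if (profile$kind == "resupply") {
    users * profile$units_per_cyp
  } else {
    users / profile$cyp_per_procedure
  }
}

#' Annual spending by sector for one method
#'
#' Splits the user stock into public/private slices by the profile's source
#' distribution, converts each slice to an annual quantity and prices it with
#' the sector's unit cost.
#'
#' @inheritParams annual_quantity
#' @return Named numeric `c(public = ..., private = ...)`, in the profile's
#'   currency.
#' @export
sector_spending <- function(profile, users) {
  if (any(users < 0)) fp_abort("users must be non-negative", "fp_domain_error")
  validate_profile_row(profile)
  users_pub <- users * profile$source_public_pct / 100
  users_priv <- users * profile$source_private_pct / 100
  c(public = annual_quantity(profile, users_pub) * profile$unit_cost_public,
    private = annual_quantity(profile, users_priv) * profile$unit_cost_private)
}

#' Build the per-method, per-sector spending table
#'
#' Applies [users_by_method()] and [sector_spending()] to every projected
#' method and assembles the costing output: one row per (method, sector) with
#' users, annual quantity and spending, plus sector totals and a grand total.
#'
#' @param projection An `fp_projection`.
#' @param profiles An `fp_method_profiles` covering every projected method.
#' @return An `fp_spending_table`: tibble with columns `method`, `sector`,
#'   `users`, `annual_quantity`, `spending`, `currency`; attributes
#'   `sector_totals` (named numeric) and `grand_total`.
#' @export
build_spending_table <- function(projection, profiles) {
  methods <- names(projection$prevalence)
  missing <- setdiff(methods, profiles$method)
  if (length(missing)) {
    fp_abort(paste("no method profile for:", paste(missing, collapse = ", ")),
             "fp_key_error")
  }
  rows <- purrr::map_dfr(methods, function(m) {
    prof <- profile_for(profiles, m)
    users <- users_by_method(projection$wra_in_union, projection$prevalence[[m]])
    split_users <- c(public = users * prof$source_public_pct / 100,
                     private = users * prof$source_private_pct / 100)
    spend <- sector_spending(prof, users)
    tibble::tibble(
      method = m,
      sector = c("public", "private"),
      users = unname(split_users),
      annual_quantity = unname(annual_quantity(prof, split_users)),
      spending = unname(spend),
      currency = prof$currency
    )
  })
  sector_totals <- c(
    public = sum(rows$spending[rows$sector == "public"]),
    private = sum(rows$spending[rows$sector == "private"])
  )
  structure(rows,
            sector_totals = sector_totals,
            grand_total = sum(sector_totals),
            class = c("fp_spending_table", class(rows)))
}

#' Totals of a spending table
#' @param table An `fp_spending_table`.
#' @return List with `sector_totals` (named numeric) and `grand_total`.
#' @export
spending_totals <- function(table) {
  list(sector_totals = attr(table, "sector_totals"),
       grand_total = attr(table, "grand_total"))
}

#' Write a spending table (CSV or JSON), totals included
#' @param table An `fp_spending_table`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_spending_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  totals <- spending_totals(table)
  if (format == "csv") {
    extra <- tibble::tibble(
      method = c("TOTAL", "TOTAL", "TOTAL"),
      sector = c("public", "private", "all"),
      users = NA_real_, annual_quantity = NA_real_,
      spending = c(unname(totals$sector_totals), totals$grand_total),
      currency = table$currency[1] %||% NA_character_
    )
    readr::write_csv(dplyr::bind_rows(tibble::as_tibble(table), extra), path)
  } else {
    jsonlite::write_json(
      list(rows = tibble::as_tibble(table),
           sector_totals = as.list(totals$sector_totals),
           grand_total = totals$grand_total),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Convert an amount between currencies at a fixed rate
#'
#' The rate is expressed as units of the local currency per unit of the
#' reference currency (e.g. IDR per USD). Direction is explicit.
#'
#' @param amount Amount to convert.
#' @param rate Positive exchange rate (local per reference).
#' @param direction `"to_reference"` (divide, e.g. IDR to USD) or `"to_local"`
#'   (multiply).
#' @return Converted amount.
#' @examples
#' convert_currency(14000, 14000, "to_reference")  # 1
#' @export
convert_currency <- function(amount, rate,
                             direction = c("to_reference", "to_local")) {
  direction <- match.arg(direction)
  if (any(rate <= 0)) fp_abort("exchange rate must be positive", "fp_domain_error")
  if (direction == "to_reference") amount / rate else amount * rate
}
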