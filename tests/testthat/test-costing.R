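resupply_profile <- function(units = 15, cpub = 1, cpriv = 2, pub = 50) {
  method_profiles(tibble::tibble(
    method = "m", kind = "resupply", units_per_cyp = units,
    cyp_per_procedure = NA, unit_cost_public = cpub, unit_cost_private = cpriv,
    source_public_pct = pub, source_private_pct = 100 - pub))[1, ]
}

procedure_profile <- function(cyp = 4.6, cpub = 10, cpriv = 20, pub = 50) {
  method_profiles(tibble::tibble(
    method = "m", kind = "long-acting", units_per_cyp = NA,
    cyp_per_procedure = cyp, unit_cost_public = cpub, unit_cost_private = cpriv,
    source_public_pct = pub, source_private_pct = 100 - pub))[1, ]
}

test_that("annual quantities follow the CYP conversion for both kinds", {
  expect_equal(annual_quantity(resupply_profile(units = 120), 100), 12000)
  expect_equal(annual_quantity(procedure_profile(cyp = 4.6), 4600), 1000)
  expect_equal(annual_quantity(resupply_profile(), 0), 0)
  expect_error(annual_quantity(resupply_profile(), -1), class = "fp_domain_error")
})

test_that("CYP conversion is algebraically invertible", {
  set.seed(21)
  for (i in 1:25) {
    users <- runif(1, 0, 1e7)
    rp <- resupply_profile(units = runif(1, 1, 200))
    pp <- procedure_profile(cyp = runif(1, 1, 13))
    expect_equal(annual_quantity(rp, users) / rp$units_per_cyp, users,
                 tolerance = 1e-9)
    expect_equal(annual_quantity(pp, users) * pp$cyp_per_procedure, users,
                 tolerance = 1e-9)
  }
})

test_that("profile kind/field mismatches are configuration errors", {
  bad <- tibble::tibble(
    method = "m", kind = "resupply", units_per_cyp = NA,
    cyp_per_procedure = 4, unit_cost_public = 1, unit_cost_private = 1,
    source_public_pct = 50, source_private_pct = 50)
  expect_error(method_profiles(bad), class = "fp_config_error")
  bad$kind <- "permanent"; bad$units_per_cyp <- 10
  expect_error(method_profiles(bad), class = "fp_config_error")
  bad2 <- resupply_profile(); bad2$source_public_pct <- 60
  expect_error(annual_quantity(bad2, 1), class = "fp_config_error")
})

test_that("sector spending splits users and prices them per sector", {
  expect_equal(sector_spending(resupply_profile(15, 1, 2, 50), 1000),
               c(public = 7500, private = 15000))
  expect_equal(sector_spending(resupply_profile(15, 1, 2, 100), 1000)[["private"]], 0)
})

test_that("sector spending matches a per-user accumulation oracle", {
  set.seed(33)
  for (i in 1:10) {
    prof <- if (i %% 2 == 0) {
      resupply_profile(units = runif(1, 1, 150), cpub = runif(1, 0.1, 50),
                       cpriv = runif(1, 0.1, 50), pub = runif(1, 0, 100))
    } else {
      procedure_profile(cyp = runif(1, 1, 13), cpub = runif(1, 1, 500),
                        cpriv = runif(1, 1, 500), pub = runif(1, 0, 100))
    }
    users <- runif(1, 0, 500)
    got <- sector_spending(prof, users)
    want <- loop_sector_spending(prof, users)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(sum(got), sum(want), tolerance = 1e-9)
  }
})

test_that("spending is monotone in users, unit cost and units per CYP", {
  set.seed(44)
  for (i in 1:10) {
    users <- runif(1, 10, 1e5)
    prof <- resupply_profile(units = runif(1, 1, 100), cpub = runif(1, 1, 10),
                             cpriv = runif(1, 1, 10), pub = runif(1, 1, 99))
    base <- sum(sector_spending(prof, users))
    expect_gte(sum(sector_spending(prof, users * 1.1)), base)
    up_cost <- prof; up_cost$unit_cost_public <- prof$unit_cost_public * 2
    expect_gte(sum(sector_spending(up_cost, users)), base)
    up_units <- prof; up_units$units_per_cyp <- prof$units_per_cyp * 1.5
    expect_gte(sum(sector_spending(up_units, users)), base)
  }
})

test_that("the spending table composes per-method calls and fills totals", {
  profiles <- method_profiles(tibble::tibble(
    method = c("a", "b"),
    kind = c("resupply", "long-acting"),
    units_per_cyp = c(12, NA), cyp_per_procedure = c(NA, 3),
    unit_cost_public = c(2, 100), unit_cost_private = c(4, 250),
    source_public_pct = c(40, 70), source_private_pct = c(60, 30)))
  series <- survey_series(
    tibble::tibble(year = 2017L, wra = 1e6, pct_in_union = 80),
    tibble::tibble(year = rep(2017L, 2), method = c("a", "b"),
                   prevalence_pct = c(20, 5)))
  proj <- project_demography(series, 2017)
  tab <- build_spending_table(proj, profiles)
  # compositionality: totals equal hand-summed per-method calls
  by_hand <- sapply(c("a", "b"), function(m) {
    sector_spending(profiles[profiles$method == m, ],
                    users_by_method(proj$wra_in_union, proj$prevalence[[m]]))
  })
  tot <- spending_totals(tab)
  expect_equal(tot$sector_totals[["public"]], sum(by_hand["public", ]))
  expect_equal(tot$sector_totals[["private"]], sum(by_hand["private", ]))
  expect_equal(tot$grand_total, sum(by_hand))
  # per-row invariant: spending = quantity x the sector's unit cost
  for (i in seq_len(nrow(tab))) {
    prof <- profiles[profiles$method == tab$method[i], ]
    cost <- if (tab$sector[i] == "public") prof$unit_cost_public else prof$unit_cost_private
    expect_equal(tab$spending[i], tab$annual_quantity[i] * cost,
                 tolerance = 1e-6)
  }
  expect_error(build_spending_table(proj, profiles[1, ]), class = "fp_key_error")
})

test_that("grand total is invariant to the sector split when costs are equal", {
  set.seed(55)
  for (pub in c(0, 25, 60, 100)) {
    prof <- resupply_profile(units = 10, cpub = 3, cpriv = 3, pub = pub)
    expect_equal(sum(sector_spending(prof, 12345)), 12345 * 10 * 3,
                 tolerance = 1e-9)
  }
})

test_that("currency conversion is explicit about direction and round-trips", {
  expect_equal(convert_currency(14000, 14000, "to_reference"), 1)
  expect_equal(convert_currency(0, 123), 0)
  x <- 987654.321
  expect_equal(convert_currency(convert_currency(x, 14000, "to_reference"),
                                14000, "to_local"), x, tolerance = 1e-9)
  expect_error(convert_currency(1, 0), class = "fp_domain_error")
})

test_that("method profile CSV round-trips, preserving kind-specific NAs", {
  profiles <- default_method_profiles()
  path <- withr::local_tempfile(fileext = ".csv")
  write_method_profiles(profiles, path)
  back <- read_method_profiles(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(profiles))
})
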