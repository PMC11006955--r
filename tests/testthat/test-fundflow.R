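fixture_edges <- function() in_paper_fixture()$ledger

test_that("matrix building sums edge amounts into stage columns", {
  m <- build_matrix(tibble::tibble(
    institution = "A", from_stage = "ORIGIN", to_stage = "NATIONAL", amount = 100))
  expect_equal(m$amounts["A", "NATIONAL"], 100)
  expect_equal(m$column_totals[["NATIONAL"]], 100)
  # two edges into one stage accumulate
  m2 <- build_matrix(tibble::tibble(
    institution = c("A", "A"), from_stage = c("ORIGIN", "ORIGIN"),
    to_stage = "NATIONAL", amount = c(40, 2)))
  expect_equal(m2$amounts["A", "NATIONAL"], 42)
})

test_that("matrix building is invariant to edge order", {
  edges <- fixture_edges()
  set.seed(99)
  for (i in 1:5) {
    shuffled <- edges[sample(nrow(edges)), ]
    expect_equal(build_matrix(shuffled)$amounts[rownames(build_matrix(edges)$amounts), ],
                 build_matrix(edges)$amounts)
    expect_equal(build_matrix(shuffled)$column_totals,
                 build_matrix(edges)$column_totals)
  }
})

test_that("absent cells stay distinct from true zeros", {
  m <- build_matrix(fixture_edges())
  expect_true(is.na(m$amounts["Ministry of Finance", "PROVINCIAL"]))
  expect_identical(m$amounts["BKKBN", "EXPENDITURE_PRIVATE"], 0)
  expect_identical(m$amounts["Other NGOs", "EXPENDITURE_PUBLIC"], 0)
})

test_that("backward or malformed flows are rejected", {
  expect_error(flow_edges(tibble::tibble(
    institution = "A", from_stage = "DISTRICT", to_stage = "NATIONAL",
    amount = 1)), class = "fp_invalid_input")
  expect_error(flow_edges(tibble::tibble(
    institution = "A", from_stage = "EXPENDITURE_PUBLIC", to_stage = "LEAKAGE",
    amount = 1)), class = "fp_invalid_input")
  expect_error(flow_edges(tibble::tibble(
    institution = "A", from_stage = "ORIGIN", to_stage = "NATIONAL",
    amount = -5)), class = "fp_invalid_input")
})

test_that("column shares normalize by their own column total", {
  m <- build_matrix(fixture_edges())
  sh <- column_shares(m)
  expect_equal(sh$shares["BKKBN", "NATIONAL"], 35.76)
  expect_equal(sh$shares["BKKBN", "PROVINCIAL"], 94.10)
  expect_equal(sh$shares["BKKBN", "DISTRICT"], 43.11)
  # single-institution column is 100.00
  solo <- build_matrix(tibble::tibble(
    institution = "A", from_stage = "ORIGIN", to_stage = "NATIONAL", amount = 7))
  expect_equal(column_shares(solo)$shares["A", "NATIONAL"], 100)
  # present shares per column sum to 100 within rounding slack
  for (s in sh$stages) {
    expect_lt(abs(sum(sh$shares[, s], na.rm = TRUE) - 100), 0.05)
  }
})

test_that("a zero column total with present entries is a division error", {
  edges <- tibble::tibble(
    institution = c("A", "A"), from_stage = c("ORIGIN", "NATIONAL"),
    to_stage = c("NATIONAL", "EXPENDITURE_PUBLIC"), amount = c(1, 0))
  expect_error(column_shares(build_matrix(edges)), class = "fp_division_error")
})

test_that("conservation flags only outflow exceeding inflow", {
  ok <- tibble::tibble(
    institution = "A",
    from_stage = c("ORIGIN", "NATIONAL", "NATIONAL"),
    to_stage = c("NATIONAL", "EXPENDITURE_PUBLIC", "LEAKAGE"),
    amount = c(100, 80, 20))
  expect_identical(nrow(validate_conservation(build_matrix(ok), ok)), 0L)

  bad <- tibble::tibble(
    institution = "A",
    from_stage = c("ORIGIN", "NATIONAL"),
    to_stage = c("NATIONAL", "EXPENDITURE_PUBLIC"),
    amount = c(100, 120))
  v <- validate_conservation(build_matrix(bad), bad)
  expect_identical(nrow(v), 1L)
  expect_equal(v$excess, 20)

  # an explicit external top-up legitimizes the extra outflow
  topped <- dplyr::bind_rows(bad, tibble::tibble(
    institution = "A", from_stage = "ORIGIN", to_stage = "NATIONAL",
    amount = 20, external = TRUE))
  expect_identical(nrow(validate_conservation(build_matrix(topped), topped)), 0L)
  # and external inflows stay out of the matrix columns
  expect_equal(build_matrix(topped)$amounts["A", "NATIONAL"], 100)
})

test_that("the published ledger flags the insurance scheme's premium-funded spending", {
  edges <- fixture_edges()
  v <- validate_conservation(build_matrix(edges), edges)
  expect_identical(v$institution, "JKN")
  expect_identical(v$stage, "DISTRICT")
  expect_equal(v$excess, 28198 + 602 - 2616)
})

test_that("implied leakage captures shrinkage along the pipeline", {
  lk <- implied_leakage(fixture_edges())
  bk <- lk[lk$institution == "BKKBN", ]
  expect_equal(bk$leakage[bk$stage == "NATIONAL"], 252736 - 225967)
  expect_equal(bk$leakage[bk$stage == "PROVINCIAL"], 225967 - 153009)
})

test_that("grouped indicators compute origin and cross-column shares", {
  m <- build_matrix(fixture_edges())
  ind <- fund_indicators(m, groups = list(
    national_budget = c("BKKBN", "Ministry of Health", "Ministry of Finance",
                        "Other ministries"),
    oop = "Out-of-pocket Payment",
    jkn = "JKN",
    everyone = m$institutions))
  expect_equal(round_half_up(ind$national_budget_share_pct, 1), 64.0)
  expect_equal(round_half_up(ind$oop_share_pct, 1), 34.6)
  expect_equal(round_half_up(ind$jkn_share_pct, 2), 0.37)
  expect_equal(round_half_up(ind$everyone_share_pct, 1), 100.0)
  expect_equal(round_half_up(ind$oop_in_public_pct, 2), 20.45)
  expect_equal(round_half_up(ind$private_expenditure_share_pct, 1), 28.6)
  expect_error(fund_indicators(m, groups = list(g = "Nobody")),
               class = "fp_key_error")
})

test_that("SankeyMATIC export is deterministic, formatted, and parses back", {
  line <- to_sankeymatic(tibble::tibble(
    institution = "BKKBN", from_stage = "NATIONAL", to_stage = "PROVINCIAL",
    amount = 225967))
  expect_identical(line, "BKKBN (national) [225967] BKKBN (provincial)")
  expect_identical(to_sankeymatic(NULL), "")

  edges <- fixture_edges()
  txt <- to_sankeymatic(edges)
  parsed <- parse_sankeymatic(txt)
  key <- function(df) {
    df <- df[order(df$institution, df$from_stage, df$to_stage), ]
    paste(df$institution, df$from_stage, df$to_stage, df$amount)
  }
  expect_identical(key(parsed),
                   key(edges[, c("institution", "from_stage", "to_stage", "amount")]))
  # shuffling input edges leaves the rendered text unchanged
  set.seed(2)
  expect_identical(to_sankeymatic(edges[sample(nrow(edges)), ]), txt)
  expect_error(to_sankeymatic(edges, node_labels = c(`BKKBN|NATIONAL` = "x")),
               class = "fp_key_error")
})

test_that("ledger CSV enforces its header and round-trips", {
  edges <- fixture_edges()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(edges, path)
  back <- read_ledger(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(edges))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("who,from,to,amt", "a,b,c,1"), bad)
  expect_error(read_ledger(bad), class = "fp_invalid_input")
})
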