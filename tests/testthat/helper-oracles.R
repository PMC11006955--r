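# Independent oracles kept deliberately naive: they must not share code with
# the implementation paths they check.

# closed-form ordinary-least-squares line through (x, y)
ols_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# per-user accumulation of sector spending: walk the users one by one (plus
# the fractional remainder) instead of using the vectorized formula
loop_sector_spending <- function(profile, users) {
  per_user <- function(cost) {
    if (profile$kind == "resupply") profile$units_per_cyp * cost
    else cost / profile$cyp_per_procedure
  }
  p_pub <- profile$source_public_pct / 100
  pub <- 0; priv <- 0
  whole <- floor(users); frac <- users - whole
  for (i in seq_len(whole)) {
    pub <- pub + p_pub * per_user(profile$unit_cost_public)
    priv <- priv + (1 - p_pub) * per_user(profile$unit_cost_private)
  }
  pub <- pub + frac * p_pub * per_user(profile$unit_cost_public)
  priv <- priv + frac * (1 - p_pub) * per_user(profile$unit_cost_private)
  c(public = pub, private = priv)
}

# minimal SankeyMATIC parser: "Label [amount] Label" with default node labels
# "<institution> (<stage lower case>)"
parse_sankeymatic <- function(text) {
  if (identical(text, "")) {
    return(tibble::tibble(institution = character(), from_stage = character(),
                          to_stage = character(), amount = numeric()))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  parse_node <- function(label) {
    m <- regmatches(label, regexec("^(.*) \\(([a-z_]+)\\)$", label))[[1]]
    c(institution = m[2], stage = toupper(m[3]))
  }
  rows <- lapply(lines, function(line) {
    m <- regmatches(line, regexec("^(.*) \\[([0-9.]+)\\] (.*)$", line))[[1]]
    src <- parse_node(m[2]); dst <- parse_node(m[4])
    tibble::tibble(institution = src[["institution"]],
                   from_stage = src[["stage"]],
                   to_stage = dst[["stage"]],
                   amount = as.numeric(m[3]))
  })
  dplyr::bind_rows(rows)
}

# two-survey series used across prevalence tests
toy_series <- function() {
  survey_series(
    demography = tibble::tibble(year = c(2010L, 2015L), wra = c(1e6, 1.1e6),
                                pct_in_union = c(70, 71)),
    prevalence = tibble::tibble(year = rep(c(2010L, 2015L), each = 1),
                                method = "pills",
                                prevalence_pct = c(50, 55))
  )
}

expected_table3 <- function() {
  # the published 2019 fund-flow matrix, USD thousands; NA = absent cell
  inst <- c("BKKBN", "Ministry of Health", "Ministry of Finance",
            "Other ministries", "JKN", "UNFPA", "Other NGOs",
            "Out-of-pocket Payment")
  m <- rbind(
    c(252736, 225967, 153009, 153009, 0),
    c(14160, 14160, 14160, 14160, 0),
    c(185111, NA, 185111, 185111, 0),
    c(258, NA, NA, 258, 0),
    c(2616, NA, 2616, 28198, 602),
    c(163, NA, NA, 163, 0),
    c(7259, NA, NA, 0, 7260),
    c(244413, NA, NA, 49988, 194425))
  dimnames(m) <- list(inst, c("NATIONAL", "PROVINCIAL", "DISTRICT",
                              "EXPENDITURE_PUBLIC", "EXPENDITURE_PRIVATE"))
  m
}
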