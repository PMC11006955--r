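#' Administrative stages of the fund flow
#'
#' Funds move ORIGIN -> NATIONAL -> PROVINCIAL -> DISTRICT and terminate in
#' one of the expenditure stages (public or private facilities) or in LEAKAGE
#' (unexecuted budget, salaries, flows the ledger cannot observe). An
#' institution may bypass intermediate levels (e.g. a ministry funding
#' districts directly), which the ledger records as an edge skipping stages.
#'
#' @return Character vector of stage names in flow order.
#' @export
fp_stages <- function() {
  c("ORIGIN", "NATIONAL", "PROVINCIAL", "DISTRICT",
    "EXPENDITURE_PUBLIC", "EXPENDITURE_PRIVATE", "LEAKAGE")
}

terminal_stages <- function() c("EXPENDITURE_PUBLIC", "EXPENDITURE_PRIVATE", "LEAKAGE")
transit_stages <- function() c("NATIONAL", "PROVINCIAL", "DISTRICT")

stage_rank <- function(stage) {
  # terminal stages share the final rank: any of them may follow any transit stage
  r <- match(stage, fp_stages())
  r[stage %in% terminal_stages()] <- length(fp_stages())
  r
}

#' Validate a fund-flow ledger
#'
#' A ledger is a table of directed flows: `institution`, `from_stage`,
#' `to_stage`, `amount` (in the ledger currency unit, conventionally USD
#' thousands), optional `currency`, `note` and `external`. `external = TRUE`
#' marks a top-up entering an institution's pipeline from outside the tracked
#' original source (e.g. an insurance scheme spending member premiums): such
#' edges count as inflow for conservation checks but are excluded from the
#' stage-column amounts so the matrix reflects the tracked budget only.
#'
#' @param edges Data frame of flows.
#' @return A validated tibble of class `fp_flow_edges`.
#' @export
flow_edges <- function(edges) {
  edges <- tibble::as_tibble(edges)
  required <- c("institution", "from_stage", "to_stage", "amount")
  missing <- setdiff(required, names(edges))
  if (length(missing)) {
    fp_abort(paste("ledger lacks columns:", paste(missing, collapse = ", ")),
             "fp_invalid_input")
  }
  if (nrow(edges) == 0L) fp_abort("ledger must contain at least one flow", "fp_invalid_input")
  if (!"currency" %in% names(edges)) edges$currency <- NA_character_
  if (!"note" %in% names(edges)) edges$note <- NA_character_
  if (!"external" %in% names(edges)) edges$external <- FALSE
  edges$external <- ifelse(is.na(edges$external), FALSE, as.logical(edges$external))
  bad_stage <- setdiff(c(edges$from_stage, edges$to_stage), fp_stages())
  if (length(bad_stage)) {
    fp_abort(paste("unknown stage:", paste(unique(bad_stage), collapse = ", ")),
             "fp_invalid_input")
  }
  if (any(edges$amount < 0)) fp_abort("flow amounts must be non-negative", "fp_invalid_input")
  if (any(edges$from_stage %in% terminal_stages())) {
    fp_abort("terminal stages cannot have outgoing flows", "fp_invalid_input")
  }
  backward <- stage_rank(edges$to_stage) <= stage_rank(edges$from_stage)
  if (any(backward)) {
    fp_abort(paste0("backward flow(s): ",
                    paste(utils::head(which(backward), 5), collapse = ", ")),
             "fp_invalid_input")
  }
  class(edges) <- c("fp_flow_edges", class(edges))
  edges
}

#' Read / write a ledger CSV
#'
#' Strict header `institution, from_stage, to_stage, amount, currency, note`
#' (an optional trailing `external` logical column is accepted).
#'
#' @param path CSV file path.
#' @return `read_ledger()`: an `fp_flow_edges` tibble.
#' @export
read_ledger <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expected <- c("institution", "from_stage", "to_stage", "amount", "currency", "note")
  if (!identical(header[seq_along(expected)], expected)) {
    fp_abort(paste0("ledger header must start with: ", paste(expected, collapse = ",")),
             "fp_invalid_input")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    institution = readr::col_character(),
    from_stage = readr::col_character(),
    to_stage = readr::col_character(),
    amount = readr::col_double(),
    currency = readr::col_character(),
    note = readr::col_character(),
    .default = readr::col_logical()
  ))
  flow_edges(raw)
}

#' @rdname read_ledger
#' @param edges An `fp_flow_edges` tibble.
#' @export
write_ledger <- function(edges, path) {
  readr::write_csv(
    edges[, c("institution", "from_stage", "to_stage", "amount", "currency",
              "note", "external")],
    path)
  invisible(path)
}

#' Build the institution-by-stage fund-flow matrix
#'
#' For every stage after ORIGIN, an institution's cell is the sum of the
#' (non-external) edge amounts entering that stage. Institutions with no edge
#' into a stage are *absent* (`NA`), which published matrices print as `"-"`
#' ("no fund channelled through this level") — distinct from a true `0`.
#' The NATIONAL column doubles as the original-source column: every
#' institution's total funding enters there from ORIGIN, whether or not it is
#' government budget.
#'
#' @param edges An `fp_flow_edges` (or data frame coercible to one).
#' @return An `fp_fundflow_matrix`: list with `amounts` (numeric matrix,
#'   institutions x stages, `NA` = absent), `column_totals`, `institutions`,
#'   `stages`.
#' @export
build_matrix <- function(edges) {
  edges <- flow_edges(edges)
  institutions <- unique(edges$institution)
  stages <- setdiff(fp_stages(), "ORIGIN")
  amounts <- matrix(NA_real_, nrow = length(institutions), ncol = length(stages),
                    dimnames = list(institutions, stages))
  tracked <- edges[!edges$external, ]
  for (i in seq_len(nrow(tracked))) {
    inst <- tracked$institution[i]
    to <- tracked$to_stage[i]
    cur <- amounts[inst, to]
    amounts[inst, to] <- if (is.na(cur)) tracked$amount[i] else cur + tracked$amount[i]
  }
  structure(list(
    amounts = amounts,
    column_totals = colSums(amounts, na.rm = TRUE),
    institutions = institutions,
    stages = stages
  ), class = "fp_fundflow_matrix")
}

#' @export
print.fp_fundflow_matrix <- function(x, ...) {
  cat("<fp_fundflow_matrix> ", length(x$institutions), " institutions x ",
      length(x$stages), " stages\n", sep = "")
  print(x$amounts)
  invisible(x)
}

#' Column shares of a fund-flow matrix
#'
#' Each cell as a percentage of its own column total, rounded half-up to two
#' decimals (the precision fund-flow tables print in brackets). Absent cells
#' stay absent; columns with no present entries are skipped.
#'
#' @param matrix An `fp_fundflow_matrix`.
#' @return An `fp_share_matrix`: list with `shares` (same shape as the
#'   amounts, percentages) and `stages` actually carrying flows.
#' @export
column_shares <- function(matrix) {
  amounts <- matrix$amounts
  shares <- amounts
  shares[] <- NA_real_
  active <- character(0)
  zero_total <- character(0)
  for (s in matrix$stages) {
    col <- amounts[, s]
    if (all(is.na(col))) next
    total <- sum(col, na.rm = TRUE)
    if (total <= 0) {
      zero_total <- c(zero_total, s)
      next
    }
    active <- c(active, s)
    shares[, s] <- round_half_up(100 * col / total, 2)
  }
  if (length(zero_total)) {
    fp_abort(paste("zero column total with present entries in stage(s):",
                   paste(zero_total, collapse = ", ")), "fp_division_error")
  }
  structure(list(shares = shares, stages = active,
                 institutions = matrix$institutions),
            class = "fp_share_matrix")
}

#' Check conservation of flows through every institution's pipeline
#'
#' At every transit stage (NATIONAL, PROVINCIAL, DISTRICT) an institution's
#' outflow must not exceed its inflow (external top-up edges count as inflow).
#' Shrinkage — inflow exceeding outflow — is legitimate: it is budget that was
#' not executed or left the tracked flow (salaries, overheads) and is treated
#' as implicit leakage. Violations are returned as data, never raised: real
#' ledgers transcribed from published tables contain rounding slack and
#' cross-scheme top-ups.
#'
#' @param matrix An `fp_fundflow_matrix` built from `edges`.
#' @param edges The `fp_flow_edges` the matrix was built from.
#' @param tol Slack allowed before outflow > inflow counts as a violation, in
#'   ledger units. Default 1: two amounts independently rounded to the printed
#'   unit (e.g. USD thousands) can disagree by up to one unit.
#' @return Tibble with columns `institution`, `stage`, `inflow`, `outflow`,
#'   `excess`; zero rows when the ledger is conservative.
#' @export
validate_conservation <- function(matrix, edges, tol = 1) {
  edges <- flow_edges(edges)
  out <- list()
  for (inst in matrix$institutions) {
    e <- edges[edges$institution == inst, ]
    for (s in transit_stages()) {
      inflow <- sum(e$amount[e$to_stage == s])
      outflow <- sum(e$amount[e$from_stage == s])
      if (outflow > inflow + tol) {
        out[[length(out) + 1L]] <- tibble::tibble(
          institution = inst, stage = s,
          inflow = inflow, outflow = outflow, excess = outflow - inflow)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(institution = character(), stage = character(),
                   inflow = numeric(), outflow = numeric(), excess = numeric())
}

#' Implicit leakage per institution
#'
#' The shrinkage (inflow minus outflow, where positive) at each transit stage,
#' i.e. funds that entered a level but were not passed on or spent. Explicit
#' LEAKAGE edges in the ledger are already outflow and are not double counted.
#'
#' @inheritParams validate_conservation
#' @return Tibble `institution`, `stage`, `leakage`.
#' @export
implied_leakage <- function(edges) {
  edges <- flow_edges(edges)
  purrr::map_dfr(unique(edges$institution), function(inst) {
    e <- edges[edges$institution == inst, ]
    purrr::map_dfr(transit_stages(), function(s) {
      inflow <- sum(e$amount[e$to_stage == s])
      outflow <- sum(e$amount[e$from_stage == s])
      if (inflow > outflow && (inflow > 0 || outflow > 0)) {
        tibble::tibble(institution = inst, stage = s, leakage = inflow - outflow)
      } else {
        tibble::tibble()
      }
    })
  })
}

#' Headline financing indicators
#'
#' Origin-column shares for named institution groups plus the cross-column
#' ratios analysts quote:
#' * `<group>_share_pct` — the group's share of the original-source column
#'   (the NATIONAL column total), for each entry of `groups`;
#' * `public_expenditure_share_pct` / `private_expenditure_share_pct` — each
#'   expenditure column's total over the original-source total;
#' * `oop_in_public_pct` — the out-of-pocket amount spent at public facilities
#'   over total out-of-pocket funding (requires a group named `"oop"`).
#'
#' Values are returned at full precision; round half-up at reporting time
#' (one decimal for headline shares, two for table-style figures).
#'
#' @param matrix An `fp_fundflow_matrix`.
#' @param groups Named list of character vectors of institution names, e.g.
#'   `list(national_budget = c("BKKBN", "Ministry of Health"), oop = "Out-of-pocket Payment")`.
#' @return Named list of class `fp_indicators`, each value in `[0, 100]`.
#' @export
fund_indicators <- function(matrix, groups = list()) {
  amounts <- matrix$amounts
  origin <- amounts[, "NATIONAL"]
  origin_total <- sum(origin, na.rm = TRUE)
  if (origin_total <= 0) fp_abort("empty original-source column", "fp_division_error")
  unknown <- setdiff(unlist(groups), matrix$institutions)
  if (length(unknown)) {
    fp_abort(paste("unknown institution(s) in groups:",
                   paste(unknown, collapse = ", ")), "fp_key_error")
  }
  ind <- list()
  for (g in names(groups)) {
    ind[[paste0(g, "_share_pct")]] <-
      100 * sum(origin[groups[[g]]], na.rm = TRUE) / origin_total
  }
  ind$public_expenditure_share_pct <-
    100 * sum(amounts[, "EXPENDITURE_PUBLIC"], na.rm = TRUE) / origin_total
  ind$private_expenditure_share_pct <-
    100 * sum(amounts[, "EXPENDITURE_PRIVATE"], na.rm = TRUE) / origin_total
  if ("oop" %in% names(groups)) {
    oop_origin <- sum(origin[groups$oop], na.rm = TRUE)
    if (oop_origin > 0) {
      ind$oop_in_public_pct <-
        100 * sum(amounts[groups$oop, "EXPENDITURE_PUBLIC"], na.rm = TRUE) / oop_origin
    }
  }
  structure(ind, class = "fp_indicators")
}

#' @export
print.fp_indicators <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("  %-35s %6.2f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Export flows as SankeyMATIC text
#'
#' One line per edge in the SankeyMATIC syntax `Source [amount] Target`.
#' Nodes are institution-at-stage; the default label is
#' `"<institution> (<stage, lower case>)"`. Lines are ordered by source stage,
#' then institution name, then target stage, so the export is deterministic.
#' Integer amounts are rendered without separators.
#'
#' @param edges An `fp_flow_edges`.
#' @param node_labels Optional named character vector mapping
#'   `"<institution>|<STAGE>"` keys to labels; when supplied it must cover
#'   every node touched by the edges.
#' @return A single string (possibly empty) of newline-separated flow lines.
#' @export
to_sankeymatic <- function(edges, node_labels = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) return("")
  edges <- flow_edges(edges)
  label_of <- function(institution, stage) {
    key <- paste0(institution, "|", stage)
    if (!is.null(node_labels)) {
      if (!key %in% names(node_labels)) {
        fp_abort(paste0("no label for node ", key), "fp_key_error")
      }
      return(unname(node_labels[key]))
    }
    paste0(institution, " (", tolower(stage), ")")
  }
  ord <- order(stage_rank(edges$from_stage), edges$institution,
               stage_rank(edges$to_stage), edges$to_stage)
  edges <- edges[ord, ]
  fmt_amount <- function(a) {
    if (abs(a - round(a)) < 1e-9) sprintf("%.0f", a)
    else sub("0+$", "", sprintf("%.9f", a))
  }
  lines <- vapply(seq_len(nrow(edges)), function(i) {
    paste0(label_of(edges$institution[i], edges$from_stage[i]),
           " [", fmt_amount(edges$amount[i]), "] ",
           label_of(edges$institution[i], edges$to_stage[i]))
  }, character(1))
  paste(lines, collapse = "\n")
}
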