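---
title: "Methods: projecting contraceptive need and tracing family-planning funds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting contraceptive need and tracing family-planning funds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpfundflow)
```

## The problem

Family-planning (FP) programs in countries like Indonesia are financed through
several channels at once: earmarked national budget flowing through a
population board and line ministries down to provinces and districts, a
national health insurance scheme reimbursing services, foreign donors and
NGOs, and households paying out of pocket (OOP) at the point of care. Questions
such as *"what share of FP funding does the insurance scheme actually
contribute?"* or *"how much OOP is spent inside public facilities that are
nominally free?"* require assembling these channels into a single
institution-by-stage **fund-flow matrix** and reading shares off its columns.

`fpfundflow` implements that analysis as a reproducible pipeline with three
inputs — a contraceptive survey series, a method-profile (costing) table, and
a budget ledger of flows — and one run report containing the demographic
projection, the CYP-based spending table, the fund-flow matrix with column
shares, headline indicators, and a conservation check.

## Demographic projection

Women of reproductive age (WRA, 15–49) are projected with geometric
compounding, $N_t = N_0 (1 + r/100)^t$, where $r$ is the annual rate of
population increase in percent. The in-union count is
$\mathrm{WRA} \times p_\text{union}/100$, with the percentage in union held at
the most recent survey's value (national series typically publish a single
value spanning adjacent years). Method-specific prevalence among in-union
women is projected linearly, in one of two modes:

* **two-point** (default): the line through the two survey rounds bracketing
  the target year — the last two rounds when extrapolating forward. Survey
  rounds are few (five in the default calendar) and recent rounds dominate the
  trend, which is why this is the default.
* **least-squares**: an ordinary linear trend over all rounds, via `lm()`.

Both modes reproduce a survey round exactly when the target year is a survey
year, and results are clamped to $[0, 100]$. The modern contraceptive
prevalence rate (mCPR) is defined as the *sum* of the per-method prevalences,
so the per-method decomposition and the total are always consistent; note
that published tables rounding each method to one decimal can print a total
that differs from the sum by 0.1.

**Published-value overrides.** National projection tables sometimes print
projected values whose exact interpolation convention is unstated (e.g. a WRA
figure interpolated from a world-population product between mid-year points).
Rather than guessing the convention, a scenario's config can pin such printed
values (`overrides: wra`, `overrides: prevalence`) so downstream tables are
reproduced verbatim while the geometric/linear model remains the default path.
The bundled Indonesia-2019 scenario uses this: 72,021,000 WRA in 2017 at the
printed 1.06 %/yr growth gives 72,784,422.6, whereas the published projection
is 72,783,702.4; the fixture carries the published value.

## CYP-based costing

Couple-years of protection (CYP) convert users into commodity or service
volumes. The profile table gives, per method:

* resupply methods (pills, condoms, injectables): `units_per_cyp` — each
  continuing user needs one CYP's worth of supplies per year, so annual
  quantity is `users × units_per_cyp`;
* long-acting and permanent methods (IUD, implant, sterilization):
  `cyp_per_procedure` — we cost the **steady state**, i.e. the annual number
  of insertions/procedures sustaining the user stock, `users /
  cyp_per_procedure`. This avoids needing acceptor-cohort data, which
  aggregated national tables do not provide.

Users are split between sectors by the method's public/private source
distribution (from the service-distribution survey), each slice converted to
a quantity and priced at the sector's unit cost. Whether a payer reimburses a
service fee-for-service or through capitation is deliberately *not* a costing
concern — it is a fund-flow concern, handled by the ledger.

The shipped default profiles use USAID-convention CYP factors (15 pill
cycles, 120 condoms, 4 three-month injections per CYP; 4.6 CYP per IUD, 2.5
per implant, 10 per sterilization). Their unit costs and sector splits are
**synthetic placeholders**: real tariffs (insurance reimbursement rates,
case-based hospital tariffs, midwife consultation fees) are country inputs
that must be supplied per scenario. The bundled fixture names its profile
file `method_profiles_synthetic.csv` for this reason, and none of the
fixture's asserted outputs depend on it.

## The fund-flow matrix

Stages are ordered `ORIGIN → NATIONAL → PROVINCIAL → DISTRICT` with three
terminal stages: public expenditure, private expenditure, and `LEAKAGE`
(budget that was allocated but not executed, or left the tracked flow as
salaries/overheads). The ledger is a list of non-negative directed edges
along this order; institutions may bypass levels (a finance ministry funding
districts directly is an edge `NATIONAL → DISTRICT`).

A matrix cell is the sum of non-external edge amounts *entering* a stage for
an institution. Two conventions matter:

* **Absent vs zero.** An institution with no edge into a stage is *absent*
  (`NA`, printed `-`: "no fund channelled through this level"), which is
  different from a true `0` (a zero-amount edge). Published matrices make
  this distinction and the data model preserves it through CSV round-trips.
* **Share base.** Each column is normalized by its *own* total, not by the
  origin total — this is how published bracketed percentages behave
  (e.g. 153,009/354,896 = 43.11 % at the district level).

Shares are rounded half-up to two decimals (`round_half_up()`; base `round()`
rounds to even and cannot reproduce printed tables). Headline indicators are
origin-column shares of named institution groups, reported half-up at one
decimal, plus cross-column ratios: sector expenditure totals over the origin
total, and OOP-in-public (OOP spent at public facilities over total OOP,
two decimals). Indicator values are kept at full precision in the report;
rounding happens at reporting time.

### Conservation and top-ups

At every transit stage, an institution's outflow must not exceed its inflow.
Shrinkage is legitimate and treated as implicit leakage (`implied_leakage()`
quantifies it). Violations are returned as data, never raised: a real ledger
transcribed from published tables *should* flag, for example, an insurance
scheme whose reimbursements (funded by member premiums outside the tracked
budget) exceed its on-budget allocation — exactly what the bundled 2019
ledger shows for JKN. Declaring such funding explicitly as an `external =
TRUE` top-up edge silences the violation while keeping the printed stage
columns intact, because external edges count as inflow but are excluded from
the matrix.

The default tolerance is 1 ledger unit: two amounts independently rounded to
the printed unit (USD thousands) can disagree by up to one unit, as the
bundled ledger's NGO row does (7,259 in, 7,260 out).

### Known irreproducibilities of the bundled table

The bundled 2019 matrix reproduces every published column total and all
headline shares exactly. A handful of printed bracketed cells are, however,
internally inconsistent with their own amounts under *any* single rounding
rule (micro-shares printed as 0.00 % where the amounts give 0.02–0.06 %, and
three cells off by one in the last digit); the package reports what the
printed amounts imply under half-up rounding, and the test suite asserts only
cells that are arithmetically consistent. Similarly, a published
public-facility headline of 57.3 % does not equal the printed
430,887/706,716 = 61.0 %; the package reports the latter and callers should
treat the public-sector expenditure share with that caveat.

## Sankey export

`to_sankeymatic()` renders the ledger as SankeyMATIC plain text, one
`Source [amount] Target` line per edge, nodes being institution-at-stage.
Ordering is deterministic (stage order, then institution, then target stage)
so exports are diffable; integer amounts render without separators. The test
suite parses the text back with an independent minimal parser and checks the
round-trip is the identity.

## Synthetic scenarios and what passing tests show

`scenario_spec()` fixes every generator parameter; one seed drives all
randomness, and each component (trends, surveys, profiles, ledger) derives
its own sub-stream from fixed offsets, so adding a component never perturbs
another's output. Defaults emulate a national FP financing study at
Indonesia's scale: five survey rounds on the DHS calendar (1997–2017)
projected to 2019, eight method categories, ~62 million WRA at the first
round growing at 1.06 %/yr, 71.9 % in union, prevalence trends with bounded
uniform noise of ±0.5 percentage points, ledgers losing 5–20 % of each
transfer to leakage and splitting terminal spending 30–70 % public.

Generated ledgers are conservative *by construction*, and the generator's own
running arithmetic (independent of the matrix code) records ground-truth
column totals, origin shares and sector indicators. Zero-noise scenarios must
be recovered exactly; noisy ones within bands that shrink as noise goes to
zero. What this does **not** show: the generator emulates aggregated national
tables only — it produces no survey microdata, no sampling weights, no
discontinuation dynamics, no stock-outs — so passing tests demonstrate the
pipeline's arithmetic and plumbing, not robustness to real survey error
structure.

Problem sizes used by the test-suite property checks are deliberately modest
— 1,000 random ledgers for the conservation sweep, 50 random profiles for the
CYP inverses, three seeds for recovery checks — chosen so the full suite runs
in well under a minute while exercising every branch.

## Numerical choices

* All intermediate quantities are kept at full double precision; rounding
  (half-up) happens only at reporting time: counts to integers, table shares
  to 2 dp, headline indicators to 1 dp.
* Prevalence clamping to $[0,100]$ happens after trend evaluation.
* Currency is a plain decimal amount tagged with a code; one fixed conversion
  rate per scenario (`convert_currency()`, direction explicit). The bundled
  scenario uses 14,000 IDR per USD.
* Degenerate inputs fail early with classed errors (`fp_domain_error`,
  `fp_config_error`, `fp_key_error`, `fp_insufficient_data`,
  `fp_division_error`), except conservation, which returns violations as data.

## Limitations

* Single fiscal year per scenario; multi-year series are the caller's loop.
* No cohort-component population projection, no unmet-need estimation, no
  unmarried-women demand.
* The costing stage prices steady-state volumes; procurement lots, wastage
  and supply-chain dynamics are out of scope.
* Ledger construction from ministry PDF reports is manual; the package
  consumes the transcribed CSV.
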