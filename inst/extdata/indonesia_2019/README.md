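# Indonesia 2019 fixture

One scenario directory in the package's standard input formats:

- `survey_series.csv` — the 2017 survey round (WRA, % in union, per-method
  modern contraceptive prevalence among in-union women).
- `config.yaml` — target year 2019, with the published projected WRA
  (72,783,702.4) and per-method 2019 prevalences pinned as overrides; the
  institution groups behind the headline indicators; the 14,000 IDR/USD rate.
- `ledger.csv` — the 2019 fund-flow matrix transcribed as flow edges, in USD
  thousands. Absent cells of the published table ("no fund channelled through
  this level") have no edge; printed zeros are zero-amount edges. JKN's
  expenditure exceeds its tracked national-budget figure (its reimbursements
  draw on member premiums outside the tracked flow), so the conservation check
  reports it — by design.
- `method_profiles_synthetic.csv` — SYNTHETIC stand-in: CYP factors follow the
  USAID convention, but the unit costs and sector splits are illustrative
  placeholders, because the study's unit-cost supplement is not available in
  machine-readable form. Spending computed from this file is demonstrative
  only; the fund-flow matrix and indicators do not depend on it.
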