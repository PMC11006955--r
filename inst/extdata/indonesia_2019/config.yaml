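# Indonesia 2019 scenario configuration.
# The projected WRA and the per-method 2019 prevalences are pinned to the
# published projection table: its exact interpolation convention is not
# stated, and the per-method 2019 values cannot be recomputed from the single
# printed survey round, so they are inputs here rather than model output.
target_year: 2019
growth_rate_pct: 1.06
prevalence_mode: two-point
currency: USD_thousands
exchange_rate_idr_per_usd: 14000
overrides:
  wra: 72783702.4
  prevalence:
    tubal ligation: 3.8
    pills: 11.9
    IUD: 4.0
    injectable: 30.9
    condoms: 2.6
    implant: 4.2
    male sterilization: 0.2
    other modern methods: 6.7
groups:
  national_budget:
    - BKKBN
    - Ministry of Health
    - Ministry of Finance
    - Other ministries
  bkkbn:
    - BKKBN
  moh:
    - Ministry of Health
  mof:
    - Ministry of Finance
  oop:
    - Out-of-pocket Payment
  jkn:
    - JKN
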