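# Demo pipeline configuration: 50,000 synthetic records with light
# contamination, three study periods, 2018 benefit thresholds.
seed: 42
simulate:
  n_records: 50000
  contamination_rates:
    female: 0.05
    early_retirement: 0.02
thresholds:
  min_eur: 657.60
  max_eur: 2617.53
periods:
  - {label: P1, start: "2005-01-01", end: "2010-12-31"}
  - {label: P2, start: "2011-01-01", end: "2014-12-31"}
  - {label: P3, start: "2015-01-01", end: "2018-12-31"}
graduation:
  method: pspline
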