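# Example pipeline configuration. Any field omitted falls back to the
# default two-year barley study design; the assay panel and taxon lists are
# user-overridable.
design:
  years: ['2020', '2021']
  fields_per_year: 3
  treatments: [fertilized, unfertilized]
  plots_per_treatment: 4
  sessions_per_year:
    '2020': 7
    '2021': 6
paths:
  detections: detections.csv
  pitfall: pitfall.csv
  tillers: tillers.csv
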