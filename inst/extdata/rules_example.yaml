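# Example rule configuration: loosen the escalation gap, disable the
# radiation-completion check, and extend the radicality table.
rules:
  - id: R1
    params:
      min_gap_days: 60
  - id: R4
    enabled: false
radicality:
  biopsy: 1
  lumpectomy: 2
  simple_mastectomy: 3
  modified_radical_mastectomy: 4
  radical_mastectomy: 5
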