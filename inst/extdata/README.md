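# Bundled fixtures

- `recurrent_variants_synthetic_coords.tsv` — per-family candidate de novo
  variant lists of a published six-family discordant-twin cohort (gene,
  HGVS labels and family memberships as reported). Genomic coordinates and
  ref/alt alleles are **synthetic**: the report prints HGVS labels only, so
  positions were invented solely to give each mutation a well-formed,
  consistent variant key.
- `recurrent_cnv_segments_synthetic_coords.tsv` — the CNV carrier lists of
  the same cohort, one segment per carrier subject. Subject IDs are
  verbatim (including `XH1535`); each subject is assigned its own family.
  Segment coordinates and gain/loss directions are **synthetic** stand-ins.
- `recurrent_cnv_gene_intervals_synthetic_coords.tsv` — matching
  **synthetic** gene intervals for the three CNV genes.
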