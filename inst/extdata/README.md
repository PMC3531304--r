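# extdata

- `jaspar_synthetic_core.pfm` — a small **synthetic** PFM library in JASPAR text
  format (12 made-up motifs, including a CTCF-like 19-mer), used as the default
  library for motif matching in examples and tests. It is not derived from any
  real motif database.
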