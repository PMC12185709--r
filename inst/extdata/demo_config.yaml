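# Demo pipeline configuration: simulate the full reciprocal-transfer design
# with default planted effects, then run every analysis stage.
# Gene-set file is synthetic, built over the simulator's fixed gene-id blocks.
seed: 42
simulate: true
dimorphism:
  organ: liver
crosstalk:
  origin: liver
  target: small_intestine
  r_thresh: 0.5
  p_thresh: 0.05
enrich:
  gmt: demo_genesets.gmt
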