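# Qualitative platform presets for the read simulator.
# gc_response: knots of the piecewise-linear fragment-GC sampling weight.
# Shapes are calibrated only to qualitative platform behaviour: the
# Illumina-like profile has mild bias and the tightest dispersion, the two
# SOLiD-like profiles drop sharply above 60% GC, and the Complete
# Genomics-like profile has the flattest GC response but the broadest
# per-locus dispersion and the weakest repeat mappability.
hiseq2000:
  gc_response: [[0.0, 0.50], [0.20, 0.80], [0.40, 1.00], [0.55, 1.00], [0.70, 0.70], [1.0, 0.40]]
  fragment_length_mean: 400
  fragment_length_sd: 40
  read_length: 100
  duplicate_rate: 0.05
  dispersion: 0.05
  repeat_mappability: 0.60
solid4:
  gc_response: [[0.0, 0.30], [0.25, 0.70], [0.40, 1.00], [0.55, 0.60], [0.65, 0.25], [0.80, 0.05], [1.0, 0.02]]
  fragment_length_mean: 230
  fragment_length_sd: 25
  read_length: 50
  duplicate_rate: 0.08
  dispersion: 0.15
  repeat_mappability: 0.60
solid5500:
  gc_response: [[0.0, 0.45], [0.25, 0.85], [0.40, 1.00], [0.55, 0.65], [0.65, 0.30], [0.80, 0.08], [1.0, 0.03]]
  fragment_length_mean: 230
  fragment_length_sd: 25
  read_length: 75
  duplicate_rate: 0.08
  dispersion: 0.12
  repeat_mappability: 0.60
cgenomics:
  gc_response: [[0.0, 0.70], [0.20, 0.90], [0.40, 1.00], [0.70, 0.95], [1.0, 0.85]]
  fragment_length_mean: 300
  fragment_length_sd: 35
  read_length: 35
  duplicate_rate: 0.03
  dispersion: 0.35
  repeat_mappability: 0.45
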