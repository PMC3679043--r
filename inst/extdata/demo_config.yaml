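# Demo evaluation: two 500 kb contigs with a human-like GC block mix
# (GC-poor stretches, balanced bulk, CpG-island-like GC-rich blocks),
# three platform profiles at 30x, one downsampling target and one
# two-platform combination experiment.
seed: 42
out_dir: null
genome:
  n_contigs: 2
  contig_length: 500000
  gc_blocks:
    - {length: 10000, gc: 0.20}
    - {length: 10000, gc: 0.35}
    - {length: 10000, gc: 0.40}
    - {length: 10000, gc: 0.45}
    - {length: 10000, gc: 0.50}
    - {length: 10000, gc: 0.40}
    - {length: 10000, gc: 0.65}
    - {length: 10000, gc: 0.45}
    - {length: 10000, gc: 0.35}
    - {length: 10000, gc: 0.75}
    - {length: 10000, gc: 0.50}
    - {length: 10000, gc: 0.30}
  n_gaps:
    - {start: 240000, length: 2000}
annotations:
  cpg_island: {rule: gc_blocks, min_gc: 0.70}
  exon: {rule: random_intervals, count: 300, width: 200}
  simple_repeat: {rule: random_intervals, count: 60, width: 400}
low_mappability: simple_repeat
tss: {count: 100}
variants: {density_per_bp: 0.001, het_fraction: 0.6}
platforms: [hiseq2000, solid4, cgenomics]
mean_coverage: 30
downsample: [15]
merge:
  - {platforms: [hiseq2000, solid4], coverages: [15, 15]}
gc_bias: {window_size: 1000, span: 0.3, gc_low: 0.25, gc_high: 0.60, grid_step: 0.005}
uncovered: {min_reads: 3}
calls: {alt_read_min: 2, depth_min: 3, fp_rate: 0.001}
size_bins: [1, 3, 10, 50, 150, 500]
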