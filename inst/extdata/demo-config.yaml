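# Demo run on a bundled simulation: two 1 Mb chromosomes, cleavable sensor.
seed: 7
out_dir: exchseq-demo-out
simulate:
  n_genes: 60
  n_ctcf: 40
  n_repeats: 20
  n_enhancers: 30
  n_hetero: 4
  chrom_lengths:
    chr1: 1000000
    chr2: 1000000
  depth: 200000
  kappa: 1
params:
  max_fragment_bp: 300
  shift_bp: 80
  depth_target: 0.4
  pseudocount: 0.05
  tile_width: 5000
  expression_bins: 4
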