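# Demo run: a small simulated cohort exercising every pipeline stage in
# under a minute. Seeds may be overridden on the command line.
seed: 101
alpha: 0.05
min_detectable: 10
cutoff: 0.5
promoter_rule: annotation
simulation:
  n_cancer: 20
  n_benign: 10
  n_healthy: 10
  include_validation: true
  n_chrom: 2
  chrom_length: 400000
  n_genes: 200
  planted_fraction: 0.05
  fragments_per_sample: 4000
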