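# Demo configuration for the full mosqnet pipeline on synthetic data.
# Run with:
#   Rscript inst/cli/mosqnet.R run --config inst/extdata/demo_config.yaml \
#     --seed 1 --out mosqnet_demo
# or from R:
#   run_all(read_run_config("inst/extdata/demo_config.yaml",
#                           out_dir = "mosqnet_demo"))
synth:
  n_samples_per_group: 10
  n_core_taxa: 15
  n_accessory_taxa_per_group: [100, 61]
  dominant_fraction: 0.9
  sequencing_depth: 50000
  n_controls: 4
contaminant_threshold: 0.5
edge_cutoff: 0.5
centrality_percentile: 75
addition_grid: [100, 300, 500, 700, 1000]
addition_reps: 2
seed: 1
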