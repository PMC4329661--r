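# Example metacompare pipeline configuration.
# Defaults (evalue 1.0e-5, floor 0.55, high 0.90, pseudocount 1,
# min_rel_sum 1.0e-4, unique_min 5) reproduce the standard analysis
# conventions; out_dir is the only required key.
seed: 42
out_dir: metacompare_run
totals: [5000, 6500]
simulate:
  sample_id: simA
  n_reads: 1000
  read_length_mean: 387
  read_length_sd: 50
  duplicate_rate: 0.05
  gc_dup_coupling: 1.0
  genomes:
    - id: methanogen_ref
      length: 50000
      gc: 0.48
      abundance: 0.6
      divergence: 0.0
      lineage:
        superkingdom: Archaea
        phylum: Euryarchaeota
        class: Methanomicrobia
    - id: clostridium_ref
      length: 50000
      gc: 0.55
      abundance: 0.4
      divergence: 0.10
      lineage:
        superkingdom: Bacteria
        phylum: Firmicutes
        class: Clostridia
qc:
  prefix_len: 50
  length_tolerance: 0.02
  gc_z: 3.0
recruit:
  k: 15
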