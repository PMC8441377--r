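reference: demo_reference.fa
guides: demo_guides.tsv
outdir: ampdel_demo_out
seed: 1
window: 60
filter:
  min_junction: 2
  min_aligned_ratio: 0.95
  min_identity: 0.95
  min_flank: 20
libraries:
  - id: rep1
    simulate: &sim
      n_reads: 2000
      wt_fraction: 0.35
      pair_fractions:
        US-3/DS-3: 0.30
        US-3/DS-1: 0.15
        US-1/DS-2: 0.10
      jitter_sd: 5
      insert_junction_prob: 0.1
      subst_error_rate: 0.003
      read_length: 150
      read_anchor_offset: 50
  - id: rep2
    simulate: *sim
  - id: rep3
    simulate: *sim
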