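# Example cohort specification for `simpre-cli.R simulate`.
# Twenty genes with a uniform background of 0.01 events/residue, two planted
# hotspots, and one of each filter confounder.
n_genes: 20
length_range: [400, 1200]
background_rate: 0.01
plants:
  - gene: 1
    start: 120
    width: 15
    fold: 25
  - gene: 7
    start: 300
    width: 10
    fold: 40
n_hypermutated: 1
n_clonal_pairs: 1
n_snp_events: 2
n_low_complexity_events: 3
rng_seed: 11
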