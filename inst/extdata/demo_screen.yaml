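# Demonstration configuration for the end-to-end pipeline:
# a small strain panel spanning the observed rate range.
screen:
  circularity_min: 0.8
  perm_area_frac: 0.5
  sel_area_frac: 0.10
  min_colonies: 10
  hyper_cutoff: 0.87
  hypo_cutoff: 0.33
sim:
  strain_rates:
    WT: 1.14e-05
    elg1: 5.09e-05
    tsa1: 1.23e-04
    sgs1: 3.75e-05
    rad54: 1.0e-06
    rad52: 0.0
    neutral1: 1.1e-05
    neutral2: 1.2e-05
  replicates: 48
integrate:
  universe: 4500
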