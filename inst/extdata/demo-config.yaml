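# Demo run: synthetic survey under the default nested design, total-biomass
# analyses end to end.
seed: 1
synthetic:
  trend: hump
analyses:
  response: biomass_kg_ha
  scope: total
  varcomp:
    n_boot: 199
  trend:
    model: time
    family: gaussian
    k: 5
  derivatives:
    grid_n: 100
  elevvar: {}
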