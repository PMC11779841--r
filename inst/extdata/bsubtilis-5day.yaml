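# "bsubtilis-5day" analysis preset: the default settings of the five-day
# static-pellicle study design. Any field omitted here falls back to the
# package defaults (see ?default_config); the scenario section is described
# in ?scenario_preset.
reference_day: 2          # density normalization anchor (relative value 1.0)
component_reference:
  category: proteins      # absolute component scale anchor ...
  day: 2                  # ... proteins on day 2 = 100
kinetics:
  classes: [protein, carbohydrate]
  interval_days: [3, 4]   # day-over-day degradation intervals
dynamics:
  delta_rigid: 22.7       # kHz, rigid-limit one-bond C-H coupling (r_CH ~ 1.1 A)
  scaling: 0.5773503      # FSLG theoretical scaling factor 1/sqrt(3)
  mas_rate: 13.5          # kHz
  powder_step: 5          # degrees, CH powder grid
  ch2_step: 10            # degrees, CH2 three-angle grid
clustering:
  days: [2, 3, 4, 5]      # day 1 excluded: medium data can be incomplete
  k_range: [2, 3, 4, 5, 6]
  seed: 0
  k: 4                    # prior-knowledge override (peptidoglycan pair distinct)
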