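# Example configuration for run_pipeline(). The dose-response and valuation
# coefficients below are ILLUSTRATIVE placeholders: they exercise the chain
# with plausible magnitudes but are not calibrated estimates. Replace them
# with study-specific values before interpreting absolute impacts.
world:
  n_regions: 10
  n_sectors: 4
  grid_shape: [36, 72]
  trade_share: 0.3
  intensity_gap: 5
  coastal_fraction: 0.5
  seed: 1
transport:
  local_fraction_peak: 0.6
  local_fraction_min: 0.2
  peak_latitude: 40
  advection_cells: 3
  advection_fraction: 0.1
  global_mixing: 0.1
  plankton_gain: 0.1
  soil_gain: 0.005
  background_D: 1
  background_P: 1
  background_S: 50
health:
  gamma: 0.5        # IQ points per (ug/g hair) — illustrative
  lambda: 0.2       # (ug/g hair) per (ug/L blood) — illustrative
  beta: 0.001       # (ug/L blood) per dose unit — illustrative
  phi: 0.05         # FHA log-linear coefficient per (ug/g hair) — illustrative
  omega: 0.5        # causality probability — illustrative
  bw: 70            # body weight, kg
  bw_mode: multiply
  el: 18832         # USD (2008) per IQ point
  vsl: 6300000      # USD (2005) per death
  deflators:
    '2008': 1.24
    '2005': 1.35
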