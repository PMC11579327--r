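# Run configuration for the packaged Salton Sea Air Basin campaign.
samples: ssab_field_samples.csv
signatures: nox_signatures.json
inventory: cepam_inventory.csv
region: imperial
fractionation:
  mode: table
  delta_table: ssab_field_samples.csv
policy:
  aggregate_mode: invert_mean_delta
  truncate_negative: true
  # reported with the regulatory inventory; not derivable from the
  # packaged signature/inventory tables (see package vignette)
  apriori_override: -5.04
  guard_band: 0.5
conversion:
  cropland_area: 270500
  fertilizer_n: 57630
delta_soil: -33.2
seed: 1
log_level: info
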