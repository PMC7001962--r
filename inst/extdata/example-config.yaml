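# Example experiment: two synthetic UK-like sites, baseline plus a 4-member
# pseudo-GCM ensemble for a high-emissions mid-century scenario.
master_seed: 1
n_years: 300
spin_up_years: 50
sowing_doy: 293          # 20 October
soil_indices: default180 # event-probability water balance (180 mm AWC)
soil_stress: hafren177   # crop stress model water balance (177 mm AWC)
cultivar:
  base_temperature: 0
  tt_sowing_to_emergence: 150
  tt_emergence_to_anthesis: 1750
  tt_anthesis_to_maturity: 800
  label: medium-ripening
sites:
  - name: east
    latitude: 52.0
    variant: default     # eastern arable site, ~650 mm/yr
  - name: west
    latitude: 52.5
    variant: wet         # western site, ~1050 mm/yr
ensemble:
  seed: 1001
  n_members: 4
  scenario: RCP8.5
  period: "2050"
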