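regime: neutral_drift
n_stations: 26.0
n_depths: 8.0
size_fractions:
- FL_0.2_3
- PA_3_8
- PA_gt8
latitude_range:
- -55.0
- 55.0
temp_peak: 29.0
temp_floor: 2.0
temp_width: 20.0
n_taxa: 200.0
meta_meanlog: 0.0
meta_sdlog: 1.5
abundance_conservatism: 0.0
lottery_sd: 0.0
guild_delta: 0.0
guild_fraction: 0.35
brownian_rate: 50.0
selection_width: Inf
dispersal_scale: Inf
community_size: 500.0
read_depth: 500.0
n_regions: 5.0
region_pool_sd: 0.0
seed: 101.0
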