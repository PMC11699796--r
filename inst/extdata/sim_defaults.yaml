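# Default synthetic-data generator configuration (see ?simulator_config).
# Any field may be overridden; omitted fields keep the documented default.
n_genes: 5000
group_sizes: [3, 4, 4, 4, 4, 4]
subpopulations: [Asia, Americas, Canada_trees, Europe_Domestic_1,
                 Europe_Domestic_2, Europe_Mix]
baseline_meanlog: 4.0
baseline_sdlog: 1.5
dispersion: 0.05
n_de_per_group: 100
de_lfc_range: [1.0, 4.0]
de_down_prob: 0.7
size_factor_sdlog: 0.15
qtt_n: 250
qtt_alpha: 1.0
qtt_positive_prob: 0.5
qtt_la_scale: 1.0
n_hidden: 1
hidden_affected_fraction: 0.3
hidden_loading_sd: 0.5
hidden_la_cor: 0.0
la_group_means: [1.0, 3.5, 3.5, 3.5, 7.5, 7.5]
la_within_sd: 0.75
lactic_glycerol_rho: -0.85
glycerol_ethanol_rho: 0.66
seed: 1
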