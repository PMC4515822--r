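seed = 20150727
n_cities = 5
n_sites = 33
sigma_log = 0.29999999999999999
sigma_ph = 0.29999999999999999
ph_c = 4.7000000000000002
ph_d = 0.25
ph_offset_throughfall = 0.29999999999999999
conc_a_so4 = 320
conc_b_so4 = -0.34999999999999998
conc_a_no3 = 42
conc_b_no3 = -0.25
conc_a_nh4 = 125
conc_b_nh4 = -0.29999999999999999
enrichment_so4 = 1.8200000000000001
enrichment_no3 = 1.5600000000000001
enrichment_nh4 = 1.3400000000000001
precip_min = 1200
precip_max = 2200
flux_h_a = 0.17000000000000001
flux_h_b = -0.57564627324851148
flux_nh4_a = 2.8475000000000001
flux_nh4_b = -0.29999999999999999
critical_radius_km = 33.973418062313229
ph_clipped = 0
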