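trait,q_rt,q_rt_lower,q_rt_upper,q_sr,q_sr_lower,q_sr_upper,published_call_rt,published_call_sr,published_level_comparison
leaf_ratio_2008,0.093,0.079,0.107,0.213,0.097,0.329,neutral,unifying,equal
leaf_ratio_2009,0.000,0.000,0.000,0.202,0.101,0.303,unifying,unifying,less
number_of_leaves,0.062,0.052,0.072,0.092,0.015,0.170,unifying,unifying,equal
number_of_inflorescences,0.106,0.097,0.116,0.030,0.022,0.038,neutral,unifying,greater
max_inflorescence_height,0.371,0.355,0.387,0.230,0.157,0.304,diversifying,unifying,greater
number_of_flowers,0.097,0.030,0.164,0.269,0.013,0.526,neutral,neutral,equal
above_ground_biomass,0.750,0.698,0.802,0.121,0.000,0.284,diversifying,unifying,greater
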