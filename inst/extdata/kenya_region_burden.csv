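admin_id,suitable_area_km2,population_at_risk,cases_mean,cases_lower,cases_upper
Central,387,38805,25,11,49
Coast,8817,270203,816,353,1612
Eastern,7003,468451,1112,495,2160
Nairobi,NA,NA,NA,NA,NA
Northeastern,2185,2539,8,3,16
Nyanza,2153,510888,2302,1061,4373
Rift Valley,1211,36090,29,14,56
Western,2649,912192,5052,2285,9696
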