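"indicator","subsystem","type_weight","comprehensive_weight"
"pop_density","P",0.1807,0.0323
"pop_growth","P",0.2297,0.0411
"edu_consolidation","P",0.3843,0.0687
"rural_employ","P",0.2053,0.0367
"fert_intensity","E",0.2103,0.058
"pest_intensity","E",0.1243,0.0343
"disaster_rate","E",0.203,0.056
"human_interference","E",0.1921,0.053
"sewage_treatment","E",0.0796,0.022
"waste_treatment","E",0.1907,0.0526
"gdp_percap","S",0.1825,0.047
"farmer_income","S",0.1847,0.0476
"tertiary_share","S",0.142,0.0366
"econ_density","S",0.2027,0.0522
"envprotect_share","S",0.2018,0.052
"land_output","S",0.0863,0.0222
"woodland_percap","N",0.3112,0.0896
"arable_percap","N",0.2842,0.0818
"grain_percap","N",0.2422,0.0697
"forest_cover","N",0.1625,0.0468
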