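"code","name","subsystem","direction","units"
"pop_density","Population density","P","negative","person/km2"
"pop_growth","Natural growth rate of population","P","negative","per mille"
"edu_consolidation","Nine-year compulsory education consolidation rate","P","positive","%"
"rural_employ","Proportion of rural employees","P","positive","%"
"fert_intensity","Chemical fertilizer application intensity","E","negative","kg/hm2"
"pest_intensity","Pesticide application intensity","E","negative","kg/hm2"
"disaster_rate","Natural disaster incidence rate","E","negative","%"
"human_interference","Human interference index","E","negative","%"
"sewage_treatment","Domestic sewage treatment rate","E","positive","%"
"waste_treatment","Domestic waste treatment rate","E","positive","%"
"gdp_percap","Per capita GDP","S","positive","10k yuan/person"
"farmer_income","Per capita net income of farmers","S","positive","yuan"
"tertiary_share","Proportion of tertiary industry in GDP","S","positive","%"
"econ_density","Economic density","S","positive","10k yuan/km2"
"envprotect_share","Proportion of environmental protection investment to GDP","S","positive","%"
"land_output","Economic output per unit of land","S","positive","10k yuan/km2"
"woodland_percap","Woodland area per capita","N","positive","hm2/person"
"arable_percap","Per capita arable land area","N","positive","hm2/person"
"grain_percap","Per capita output of grain","N","positive","kg/person"
"forest_cover","Percentage of forest cover","N","positive","%"
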