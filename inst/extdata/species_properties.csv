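name,formula,phase,molar_mass_g_mol,h_form_298_kJ_kmol,s_298_kJ_kmol_K,h_sens_298_kJ_kmol,h_sens_310_kJ_kmol,s_310_kJ_kmol_K,note
glucose,C6H12O6,solid,180,-1260000,212,NA,NA,NA,dietary carbohydrate surrogate; sensible enthalpy 298-310 K neglected for condensed species
palmitate,C16H32O2,solid,256,-835000,452,NA,NA,NA,dietary fat surrogate; sensible enthalpy 298-310 K neglected for condensed species
amino,C4.57H9.03N1.27O2.25S0.046,solid,119,-385000,166.719,NA,NA,NA,average of the 20 proteinogenic amino acids; s = 1.401 kJ/(kg K) x 119 g/mol
O2,O2,gas,32,0,218,8682,9030,220,inhaled at 298 K; sensible enthalpies from standard ideal-gas tables
CO2,CO2,gas,44,-393520,213.8,9364,9807,243,exhaled at 310 K; h_form and h_sens(298) from standard ideal-gas tables
H2O,H2O,gas,18,-241820,188.8,9904,10302,219,metabolic water leaving as vapour at 310 K; h_form and h_sens(298) from standard ideal-gas tables
H2O_liq,H2O,liquid,18,-285830,69.9,NA,NA,69.9,liquid water (urine phase); recorded for reference; dietary/urinary water cancels in the balance
urea,CH4N2O,solid,60,-333100,104.6,NA,NA,104.6,nitrogen carrier of amino-acid oxidation; standard-table values; condensed-phase temperature correction neglected
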