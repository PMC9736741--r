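farm,area_ha,density_tco2e_ha,reserves_tco2e,note
Longxi Town,2074.5,75.64,156924,
Xinjiang Town,1653.9,65.12,107701,
State Business,2643.9,85.63,226388,
Source Feng,2038.6,70.39,14347,area rescaled from a printed 20386 ha that is inconsistent with the printed reserves; excluded from reproduction checks
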