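farm,year,species,stock_volume_m3,stems,area_ha,shrub_cover,region
Longxi Town,2022,eucalyptus,9836,,2074.5,0,south China
Longxi Town,2022,Chinese red pine,21228,,2074.5,0,south China
Longxi Town,2022,Soft broad class,43502,,2074.5,0,south China
Longxi Town,2022,China fir,10096,,2074.5,0,south China
Longxi Town,2022,Needle wide mix,12089,,2074.5,0,south China
Longxi Town,2022,Needle leaf mix,863,,2074.5,0,south China
Xinjiang Town,2022,eucalyptus,25441,,1653.9,0,south China
Xinjiang Town,2022,Chinese red pine,15463,,1653.9,0,south China
Xinjiang Town,2022,China fir,30960,,1653.9,0,south China
State Business,2022,eucalyptus,107098,,2643.9,0,south China
State Business,2022,Chinese red pine,5629,,2643.9,0,south China
State Business,2022,Soft broad class,15248,,2643.9,0,south China
State Business,2022,China fir,442,,2643.9,0,south China
State Business,2022,Hard broad class,9343,,2643.9,0,south China
State Business,2022,Needle wide mix,1492,,2643.9,0,south China
State Business,2022,Castanopsis fissa,1073,,2643.9,0,south China
Source Feng,2022,eucalyptus,57896,,2038.6,0,south China
Source Feng,2022,Chinese red pine,681,,2038.6,0,south China
Source Feng,2022,Soft broad class,15248,,2038.6,0,south China
Source Feng,2022,China fir,442,,2038.6,0,south China
Source Feng,2022,Hard broad class,9343,,2038.6,0,south China
Source Feng,2022,Needle leaf mix,1492,,2038.6,0,south China
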