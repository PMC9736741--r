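species_id,wood_density,bef,root_shoot_ratio,carbon_fraction,product_wood_density,product_carbon_fraction,litter_group
eucalyptus,0.578,1.263,0.221,0.525,0.578,0.525,eucalyptus
Chinese red pine,0.380,1.472,0.254,0.511,0.380,0.511,Chinese red pine
Soft broad class,0.443,1.586,0.289,0.480,0.443,0.480,Other soft broad
China fir,0.307,1.634,0.246,0.520,0.307,0.520,Cedar trees and other Chinese fir species
Hard broad class,0.598,1.674,0.261,0.490,0.598,0.490,Other hard broad class
Needle wide mix,0.482,1.586,0.262,0.510,0.482,0.510,
Needle leaf mix,0.410,1.560,0.266,0.510,0.410,0.510,
Castanopsis fissa,0.598,1.674,0.261,0.490,0.598,0.490,Other hard broad class
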