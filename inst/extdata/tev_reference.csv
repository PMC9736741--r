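farm,land_value_wan,tree_value_wan,carbon_fixation_value_wan,habitat_value_wan
Longxi Town,429.83,4914.14,59.41,15.93
Xinjiang Town,392.31,3969.97,67.48,12.70
State Business,627.13,5798.75,18.63,20.30
Source Feng,483.56,3727.58,44.87,15.66
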