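product_class,waste_rate,service_life_yr
building,0.35,50
sawnwood,0.40,35
furniture,0.38,30
panel,0.45,25
paper,0.60,2
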