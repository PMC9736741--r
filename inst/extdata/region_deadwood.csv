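region,dfdw
northeast,0.0351
NC,0.0206
Inner Mongolia,0.0351
Central Plains,0.0206
Central China,0.0225
south China,0.0225
southwest,0.0188
northwest,0.0311
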