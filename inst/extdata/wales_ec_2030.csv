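"","broadleaf forest","conifer forest","arable land","improved grassland","semi-natural grassland","mountain heath and bog"
"broadleaf forest",1,0,0,0,0,0
"conifer forest",0.282,0.659,0.003,0.029,0.020,0.004
"arable land",0.052,0.009,0.098,0.752,0.079,0.007
"improved grassland",0.040,0.008,0.057,0.784,0.103,0.006
"semi-natural grassland",0.073,0.049,0.034,0.411,0.381,0.051
"mountain heath and bog",0.061,0.088,0.019,0.167,0.347,0.316
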