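name,cramers_v,type
altitude,0.345,static
aspect,0.077,static
slope,0.168,static
hillshade,0.135,static
distance from access points,0.224,static
distance from green spaces,0.223,static
distance from water channels,0.011,static
distance from roads,0.254,static
distance from hydronodes,0.065,static
distance from motorway junctions,0.161,static
distance from broadleaf forest,0.155,dynamic
distance from conifer forest,0.081,dynamic
distance from arable land,0.21,dynamic
distance from improved grassland,0.155,dynamic
distance from semi-natural grassland,0.161,dynamic
distance from mountain heath and bog,0.013,dynamic
evidence likelihood broadleaf to all (transition),0.249,static
evidence likelihood all to broadleaf (transition),0.533,static
evidence likelihood broadleaf to all (soil),0.251,static
evidence likelihood all to broadleaf (soil),0.256,static
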