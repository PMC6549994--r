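code,name
1,broadleaf forest
2,conifer forest
3,arable land
4,improved grassland
5,semi-natural grassland
6,mountain heath and bog
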