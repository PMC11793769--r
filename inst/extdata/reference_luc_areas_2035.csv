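"land_use","area_2020","SSP126","SSP245","SSP585"
"farmland",13991.32,13773.04,13759.24,13750.96
"forest",38543.17,38310.38,38353.82,38277.55
"grassland",17895.12,17608.01,17584.59,17609.27
"water",516.38,1054.01,765.81,819.07
"builtup",904.95,1162.91,1408.05,1430
"unused",76.87,19.47,56.31,40.96
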