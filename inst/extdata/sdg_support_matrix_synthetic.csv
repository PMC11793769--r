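"es","SDG1","SDG2","SDG3","SDG4","SDG5","SDG6","SDG7","SDG8","SDG9","SDG10","SDG11","SDG12","SDG13","SDG14","SDG15","SDG16","SDG17"
"habitat_quality",2,4,2,0,0,3,0,2,0,0,3,3,2,4,4,0,0
"carbon_storage",0,2,0,0,0,0,4,0,2,0,2,3,4,0,2,0,0
"water_yield",2,3,2,0,0,5,2,0,2,0,3,2,0,2,2,0,0
"soil_retention",0,0,0,0,0,4,0,0,0,0,0,0,0,0,5,0,0
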