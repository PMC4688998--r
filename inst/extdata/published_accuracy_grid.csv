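family,family_size,trait,pearson_r
AF1_Da66,662,attractiveness,0.21
AF1_Da66,662,fruit_cropping,0.08
AF1_Da66,662,fruit_size,0.26
AF1_Da66,662,percent_russet,0.18
AF1_Da66,662,fruit_cracking,-0.09
AF1_Da66,662,percent_over_colour,0.31
AF1_Da66,662,over_colour,0.34
AF1_Da66,662,ground_colour,-0.03
AF1_Da66,662,type_of_colour,-0.06
AF2_Pi63,172,attractiveness,0.18
AF2_Pi63,172,fruit_cropping,0.09
AF2_Pi63,172,fruit_size,0.19
AF2_Pi63,172,percent_russet,0.21
AF2_Pi63,172,fruit_cracking,-0.05
AF2_Pi63,172,percent_over_colour,0.22
AF2_Pi63,172,over_colour,0.17
AF2_Pi63,172,ground_colour,0.12
AF2_Pi63,172,type_of_colour,0.00
AF3_31Fu,269,attractiveness,0.35
AF3_31Fu,269,fruit_cropping,0.02
AF3_31Fu,269,fruit_size,0.08
AF3_31Fu,269,percent_russet,0.38
AF3_31Fu,269,fruit_cracking,0.13
AF3_31Fu,269,preharvest_dropping,0.02
AF3_31Fu,269,percent_over_colour,0.50
AF3_31Fu,269,over_colour,0.44
AF3_31Fu,269,ground_colour,0.09
AF3_31Fu,269,type_of_colour,-0.25
AF4_31Ga,109,attractiveness,0.19
AF4_31Ga,109,fruit_cropping,0.19
AF4_31Ga,109,fruit_size,0.33
AF4_31Ga,109,percent_russet,0.30
AF4_31Ga,109,fruit_cracking,-0.02
AF4_31Ga,109,preharvest_dropping,-0.06
AF4_31Ga,109,percent_over_colour,0.46
AF4_31Ga,109,over_colour,0.49
AF4_31Ga,109,ground_colour,-0.05
AF4_31Ga,109,type_of_colour,-0.23
AF5_33Br,178,attractiveness,0.14
AF5_33Br,178,fruit_cropping,0.03
AF5_33Br,178,fruit_size,0.25
AF5_33Br,178,percent_russet,-0.06
AF5_33Br,178,fruit_cracking,0.07
AF5_33Br,178,preharvest_dropping,-0.02
AF5_33Br,178,percent_over_colour,0.36
AF5_33Br,178,over_colour,0.32
AF5_33Br,178,ground_colour,0.17
AF5_33Br,178,type_of_colour,-0.14
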