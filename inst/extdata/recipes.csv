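recipe_id,product,ingredient,share,role
B1,beef,soy_protein_isolate,0.20,protein
B1,beef,sweet_potato_dried,0.06,binder
B1,beef,vegetable_oil,0.20,oil
B2,beef,rapeseed_protein_isolate,0.20,protein
B2,beef,cane_syrup,0.06,binder
B2,beef,vegetable_oil,0.20,oil
B3,beef,potato_protein_isolate,0.15,protein
B3,beef,peanut_flour,0.15,protein
B3,beef,vegetable_oil,0.20,oil
B4,beef,soy_protein_isolate,0.10,protein
B4,beef,potato_protein_isolate,0.06,protein
B4,beef,wheat_protein_concentrate,0.04,protein
B4,beef,vegetable_oil,0.20,oil
B5,beef,soy_protein_isolate,0.20,protein
B5,beef,cassava_raw,0.10,binder
B5,beef,vegetable_oil,0.20,oil
C1,chicken,soy_protein_isolate,0.13,protein
C1,chicken,chickpea_protein,0.13,protein
C1,chicken,wheat_flour,0.10,binder
C1,chicken,vegetable_oil,0.08,oil
C2,chicken,soy_protein_isolate,0.20,protein
C2,chicken,sweet_potato_dried,0.10,binder
C2,chicken,vegetable_oil,0.08,oil
P1,pork,beans_dry,0.15,protein
P1,pork,soy_protein_isolate,0.13,protein
P1,pork,sorghum_flour,0.04,binder
P1,pork,vegetable_oil,0.20,oil
P2,pork,soy_protein_isolate,0.20,protein
P2,pork,wheat_flour,0.04,binder
P2,pork,vegetable_oil,0.20,oil
M1,milk,soy_protein_concentrate,0.07,protein
M1,milk,cane_syrup,0.02,binder
M1,milk,vegetable_oil,0.03,oil
M2,milk,rapeseed_meal,0.07,protein
M2,milk,wheat_protein_concentrate,0.03,protein
M2,milk,vegetable_oil,0.02,oil
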