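trait,term,category,specificity,generalization
metabolism,aerobic,aerobic-group,1,aerobic
metabolism,obligate aerobic,aerobic-group,2,aerobic
metabolism,facultative aerobic,aerobic-group,2,aerobic
metabolism,microaerophilic,aerobic-group,2,aerobic
metabolism,anaerobic,anaerobic-group,1,anaerobic
metabolism,obligate anaerobic,anaerobic-group,2,anaerobic
metabolism,facultative anaerobic,anaerobic-group,2,anaerobic
motility,yes,motile-group,1,yes
motility,flagella,motile-group,2,yes
motility,gliding,motile-group,2,yes
motility,axial filament,motile-group,2,yes
motility,no,non-motile-group,1,no
gram_stain,positive,positive,1,positive
gram_stain,negative,negative,1,negative
gram_stain,variable,variable,1,variable
sporulation,yes,yes,1,yes
sporulation,no,no,1,no
cell_shape,rod,rod,1,rod
cell_shape,coccus,coccus,1,coccus
cell_shape,coccobacillus,coccobacillus,1,coccobacillus
cell_shape,spirillum,spirillum,1,spirillum
cell_shape,vibrio,vibrio,1,vibrio
cell_shape,filament,filament,1,filament
cell_shape,spirochete,spirochete,1,spirochete
cell_shape,pleomorphic,pleomorphic,1,pleomorphic
range_tmp,psychrophilic,psychrophilic,1,psychrophilic
range_tmp,mesophilic,mesophilic,1,mesophilic
range_tmp,thermophilic,thermophilic,1,thermophilic
range_tmp,hyperthermophilic,hyperthermophilic,1,hyperthermophilic
range_salinity,non-halophilic,non-halophilic,1,non-halophilic
range_salinity,halotolerant,halotolerant,1,halotolerant
range_salinity,halophilic,halophilic,1,halophilic
range_salinity,extreme-halophilic,extreme-halophilic,1,extreme-halophilic
pathways,fermentation,fermentation,1,fermentation
pathways,methanogenesis,methanogenesis,1,methanogenesis
pathways,nitrogen_fixation,nitrogen_fixation,1,nitrogen_fixation
pathways,denitrification,denitrification,1,denitrification
pathways,sulfate_reduction,sulfate_reduction,1,sulfate_reduction
pathways,sulfur_oxidation,sulfur_oxidation,1,sulfur_oxidation
pathways,nitrification,nitrification,1,nitrification
pathways,photoautotrophy,photoautotrophy,1,photoautotrophy
pathways,methylotrophy,methylotrophy,1,methylotrophy
pathways,iron_oxidation,iron_oxidation,1,iron_oxidation
carbon_substrates,glucose,glucose,1,glucose
carbon_substrates,fructose,fructose,1,fructose
carbon_substrates,sucrose,sucrose,1,sucrose
carbon_substrates,lactose,lactose,1,lactose
carbon_substrates,maltose,maltose,1,maltose
carbon_substrates,acetate,acetate,1,acetate
carbon_substrates,lactate,lactate,1,lactate
carbon_substrates,citrate,citrate,1,citrate
carbon_substrates,glycerol,glycerol,1,glycerol
carbon_substrates,ethanol,ethanol,1,ethanol
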