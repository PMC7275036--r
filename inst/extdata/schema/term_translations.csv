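trait,from,to
sporulation,spore-forming,yes
sporulation,spore forming,yes
sporulation,sporulating,yes
sporulation,non-spore-forming,no
sporulation,nonsporulating,no
sporulation,non-sporulating,no
gram_stain,gram-positive,positive
gram_stain,gram positive,positive
gram_stain,gram+,positive
gram_stain,gram-negative,negative
gram_stain,gram negative,negative
gram_stain,gram-,negative
gram_stain,gram-variable,variable
metabolism,aerobe,aerobic
metabolism,anaerobe,anaerobic
metabolism,obligate aerobe,obligate aerobic
metabolism,strictly aerobic,obligate aerobic
metabolism,obligate anaerobe,obligate anaerobic
metabolism,strictly anaerobic,obligate anaerobic
metabolism,facultative aerobe,facultative aerobic
metabolism,facultative anaerobe,facultative anaerobic
metabolism,facultative,facultative anaerobic
metabolism,microaerophile,microaerophilic
motility,motile,yes
motility,non-motile,no
motility,nonmotile,no
motility,not motile,no
motility,flagellar,flagella
motility,flagellated,flagella
cell_shape,bacillus,rod
cell_shape,rod-shaped,rod
cell_shape,rods,rod
cell_shape,cocci,coccus
cell_shape,sphere,coccus
cell_shape,spiral,spirillum
cell_shape,filamentous,filament
range_tmp,psychrophile,psychrophilic
range_tmp,mesophile,mesophilic
range_tmp,thermophile,thermophilic
range_tmp,hyperthermophile,hyperthermophilic
range_salinity,halophile,halophilic
range_salinity,halotolerant organism,halotolerant
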