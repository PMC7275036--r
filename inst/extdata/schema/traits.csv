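name,kind,dtype,unit
gram_stain,phenotypic,binary_categorical,
metabolism,phenotypic,multilevel_categorical,
pathways,phenotypic,multiset_categorical,
carbon_substrates,phenotypic,multiset_categorical,
sporulation,phenotypic,binary_categorical,
motility,phenotypic,multilevel_categorical,
range_tmp,phenotypic,binary_categorical,
range_salinity,phenotypic,binary_categorical,
cell_shape,phenotypic,binary_categorical,
isolation_source,environmental,hierarchical_label,
d1_lo,phenotypic,numeric,µm
d1_up,phenotypic,numeric,µm
d2_lo,phenotypic,numeric,µm
d2_up,phenotypic,numeric,µm
doubling_h,phenotypic,numeric,h
genome_size,genomic,numeric,bp
gc_content,genomic,numeric,percent
coding_genes,genomic,numeric,count
optimum_tmp,environmental,numeric,°C
optimum_ph,environmental,numeric,pH
growth_tmp,environmental,numeric,°C
rRNA16S_genes,genomic,numeric,count
tRNA_genes,genomic,numeric,count
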