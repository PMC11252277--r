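taxon_id,shape,length_um,width_um
glaucoma_scintillans,sphere,55,
didinium_nasutum,oval,120,80
euplotes_muscicola,ellipsoid,80,45
paradileptus_elephantinus,cone,250,110
strobilidium_spiralis,cylinder,60,45
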