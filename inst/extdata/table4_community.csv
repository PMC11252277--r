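taxon_id,name,phylum,saprobity_code,feeding_guild,abund_I,abund_II,abund_III,abund_IV,abund_V,abund_VI,biom_I,biom_II,biom_III,biom_IV,biom_V,biom_VI,abund_avg,biom_avg,dominant_sites,site_assignment_uncertain,has_reconstructed_cell
amoeba_proteus,Amoeba proteus,Amoebozoa,b,,0,8.33,33.33,25,8.33,8.33,0,0.08,1.57,1.51,0.28,0.37,13.89,0.64,,TRUE,FALSE
amoeba_verrucosa,Amoeba verrucosa,Amoebozoa,,,0,0,33.33,0,0,0,0,0,5.15,0,0,0,5.56,0.86,,TRUE,FALSE
amoeba_villosa,Amoeba villosa,Amoebozoa,a-b,,0,33.33,16.67,16.67,16.67,33.33,0,7.6,13.93,4.95,18.36,4.33,19.44,8.2,,TRUE,FALSE
hartmannella_limacoides,Hartmannella limacoides,Amoebozoa,,,0,0,0,0,0,8.33,0,0,0,0,0,0.01,1.39,0.0017,,TRUE,FALSE
centropyxis_aculeata,Centropyxis aculeata,Amoebozoa,b,,0,0,0,0,0,41.67,0,0,0,0,0,2.1,6.94,0.35,VI,FALSE,FALSE
cocholipodium_bilimbosum,Cocholipodium bilimbosum,Amoebozoa,,,0,0,0,0,8.33,0,0,0,0,0,1.85,0,1.39,0.31,,TRUE,FALSE
cryptodifflugia_oviformis,Cryptodifflugia oviformis,Amoebozoa,,,0,0,8.33,0,0,0,0,0,0.01,0,0,0,1.39,0.0017,,TRUE,FALSE
difflugia_lobostoma,Difflugia lobostoma,Amoebozoa,a-b,,0,0,0,0,0,8.33,0,0,0,0,0,0.24,1.39,0.04,,TRUE,FALSE
pelomyxa_gruberi,Pelomyxa gruberi,Amoebozoa,p-i,,0,0,0,0,0,8.33,0,0,0,0,0,3.43,1.39,0.57,,TRUE,FALSE
quadrulella_symmetrica,Quadrulella symmetrica,Amoebozoa,,,0,0,8.33,0,0,0,0,0,0.43,0,0,0,1.39,0.07,,TRUE,FALSE
nuclearia_delicatula,Nuclearia delicatula,Choanozoa,,,33.33,25,16.67,25,8.33,25,0.22,0.17,0.16,0.21,0.06,0.19,22.22,0.17,,FALSE,FALSE
nuclearia_moebius,Nuclearia moebius,Choanozoa,,,8.33,8.33,0,0,0,0,0.72,0.11,0,0,0,0,2.78,0.14,,TRUE,FALSE
nuclearia_simplex,Nuclearia simplex,Choanozoa,,,0,8.33,0,0,0,0,0,0.04,0,0,0,0,1.39,0.01,,TRUE,FALSE
pinaciophora_fluviatilis,Pinaciophora fluviatilis,Choanozoa,,,0,8.33,0,0,0,0,0,0.06,0,0,0,0,1.39,0.01,,TRUE,FALSE
acanthocystis_pectinata,Acanthocystis pectinata,Heliozoa,,,8.33,8.33,16.67,8.33,8.33,0,0.96,0.63,1.26,0.96,0.46,0,8.33,0.71,,TRUE,FALSE
acanthocystis_turfacea,Acanthocystis turfacea,Heliozoa,,,83.33,66.67,75,83.33,41.67,58.33,0.18,0.15,0.16,0.18,0.09,0.13,68.06,0.15,I,FALSE,FALSE
heterophrys_myriapoda,Heterophrys myriapoda,Heliozoa,,,50,33.33,0,25,16.67,0,3.61,2.44,0,2.32,1.45,0,20.83,1.64,,TRUE,FALSE
pompholyxophrys_punicea,Pompholyxophrys punicea,Heliozoa,,,25,58.33,8.33,33.33,8.33,8.33,0.35,0.86,0.15,0.45,0.15,0.14,23.61,0.35,,FALSE,TRUE
cyphoderia_ampulla,Cyphoderia ampulla,Cercozoa,,,0,0,0,0,0,16.67,0,0,0,0,0,0.51,2.78,0.09,,TRUE,FALSE
euglypha_tuberculata,Euglypha tuberculata,Cercozoa,,,0,8.33,0,0,0,0,0,0.43,0,0,0,0,1.39,0.07,,TRUE,FALSE
pamphagus_hyalinus,Pamphagus hyalinus,Cercozoa,,,16.67,0,0,0,0,0,0.12,0,0,0,0,0,2.78,0.02,,TRUE,FALSE
trinema_lineare,Trinema lineare,Cercozoa,,,16.67,0,0,0,0,16.67,0.05,0,0,0,0,0.41,5.56,0.08,,TRUE,FALSE
vampyrella_sp,Vampyrella sp.,Cercozoa,,,0,0,16.67,0,0,0,0,0,0.09,0,0,0,2.78,0.01,,TRUE,FALSE
dinamoeba_mirabilis,Dinamoeba mirabilis,Myzozoa,,,16.67,0,0,0,0,0,2.06,0,0,0,0,0,2.78,0.34,,TRUE,FALSE
askenasia_volvox,Askenasia volvox,Ciliophora,b,"Al, Ki",0,16.67,8.33,0,8.33,8.33,0,0.57,0.1,0,0.96,0.9,6.94,0.42,,TRUE,FALSE
bursaria_truncatella,Bursaria truncatella,Ciliophora,a-b,O,0,0,50,0,0,0,0,0,26.94,0,0,0,8.33,4.49,,TRUE,FALSE
bursaridium_schewakoffi,Bursaridium schewakoffi,Ciliophora,,,0,66.67,66.67,66.67,41.67,0,0,22.03,16.37,26.55,17.39,0,40.28,13.72,,TRUE,FALSE
caenomorpha_lauterborni,Caenomorpha lauterborni,Ciliophora,p-m,"Ba, Sb",0,0,0,0,0,8.33,0,0,0,0,0,0.15,1.39,0.03,,FALSE,FALSE
cinetochilum_margaritaceum,Cinetochilum margaritaceum,Ciliophora,p-i,"Ba, Al",41.67,8.33,0,33.33,0,16.67,0.06,0.01,0,0.04,0,0.02,16.67,0.02,,TRUE,FALSE
colpidium_colpoda,Colpidium colpoda,Ciliophora,p-i,"Ba, Fl, Al",8.33,100,133.3,16.67,83.33,0,0.66,5.86,12.65,1.48,6.23,0,56.94,4.48,II;III,TRUE,FALSE
cyclidium_heptatrichum,Cyclidium heptatrichum,Ciliophora,b,Ba,0,0,8.33,0,0,0,0,0,0.03,0,0,0,1.39,0.005,,TRUE,FALSE
didinium_nasutum,Didinium nasutum,Ciliophora,a-b,R,50,41.67,66.67,108.3,233.3,25,6.02,4.64,9.01,8.93,13.2,1.2,87.5,7.17,III;IV;V,FALSE,FALSE
dileptus_anser,Dileptus anser,Ciliophora,,,16.67,0,16.67,0,0,8.33,0.55,0,2.83,0,0,0.1,6.94,0.58,,TRUE,FALSE
euplotes_muscicola,Euplotes muscicola,Ciliophora,,,8.33,0,0,0,0,0,1.43,0,0,0,0,0,1.39,0.24,,TRUE,FALSE
glaucoma_scintillans,Glaucoma scintillans,Ciliophora,p-a,Ba,66.67,0,41.67,16.67,50,125,6.75,0,2.12,0.12,2.5,25.62,50,6.18,I;VI,TRUE,FALSE
lacrymaria_lagenula,Lacrymaria lagenula,Ciliophora,,,0,0,0,0,0,8.33,0,0,0,0,0,0.43,1.39,0.07,,TRUE,FALSE
lacrymaria_olor,Lacrymaria olor,Ciliophora,b,R,0,8.33,33.33,33.33,0,0,0,0.56,7.32,1.45,0,0,12.5,1.55,,TRUE,FALSE
leegaardiella_sp,Leegaardiella sp.,Ciliophora,,,0,8.33,0,0,8.33,0,0,0.43,0,0,0.4,0,2.78,0.14,,TRUE,FALSE
lohmanniella_oviformis,Lohmanniella oviformis,Ciliophora,,,8.33,0,41.67,83.33,66.67,0,0.06,0,0.22,0.37,0.33,0,33.33,0.16,IV;V,TRUE,FALSE
mesodinium_pulex,Mesodinium pulex,Ciliophora,b,O,16.67,33.33,16.67,125,91.67,16.67,0.2,0.49,0.29,1.49,1.1,0.2,50,0.63,IV;V,FALSE,FALSE
mesodinium_rubrum,Mesodinium rubrum,Ciliophora,,,0,33.33,16.67,25,0,0,0,0.16,0.07,0.07,0,0,12.5,0.05,,TRUE,FALSE
monodinium_balbiani,Monodinium balbiani,Ciliophora,o-a,R,133.3,33.33,58.33,66.67,75,0,5.04,1.09,1.78,2.69,2.57,0,61.11,2.23,I;IV;V,TRUE,FALSE
paradileptus_elephantinus,Paradileptus elephantinus,Ciliophora,b,O,175,283.3,358.3,258.33,125,75,10.99,30.65,48.4,22.37,9.1,5.04,212.5,21.09,I;II;III;IV;V;VI,FALSE,FALSE
paramecium_aurelia,Paramecium aurelia,Ciliophora,a-b,Ba,0,8.33,16.67,0,0,0,0,0.11,0.55,0,0,0,4.17,0.11,,TRUE,FALSE
paramecium_bursaria,Paramecium bursaria,Ciliophora,a-b,"Ba, Al, Ki",0,0,0,16.67,0,0,0,0,0,2.13,0,0,2.78,0.35,,TRUE,FALSE
phascolodon_vorticella,Phascolodon vorticella,Ciliophora,a-b,"Al, Ki",33.33,0,16.67,16.67,0,0,0.8,0,0.51,0.4,0,0,11.11,0.29,,TRUE,FALSE
prorodon_ellipticus,Prorodon ellipticus,Ciliophora,a-b,R,58.33,0,50,25,0,0,5.47,0,8.08,0.81,0,0,22.22,2.39,,TRUE,FALSE
stentor_roeseli,Stentor roeseli,Ciliophora,a-b,O,8.33,0,0,0,0,0,0.12,0,0,0,0,0,1.39,0.02,,TRUE,FALSE
strobilidium_caudatum,Strobilidium caudatum,Ciliophora,o-b,"Ki, Al, Ba",16.67,16.67,8.33,16.67,16.67,0,0.04,0.16,0.58,0.25,0.05,0,12.5,0.18,,TRUE,TRUE
strobilidium_spiralis,Strobilidium spiralis,Ciliophora,,,8.33,8.33,0,16.67,0,0,0.11,0.11,0,0.29,0,0,5.56,0.08,,TRUE,FALSE
strombidium_stylifer,Strombidium stylifer,Ciliophora,,,0,0,25,33.33,0,33.33,0,0,1.71,1.05,0,0.58,15.28,0.56,,TRUE,FALSE
stylonychia_pustulata,Stylonychia pustulata,Ciliophora,b,O,25,16.67,8.33,58.33,33.33,0,5.45,1.83,1.29,5.53,6.24,0,23.61,3.39,,TRUE,FALSE
urotricha_globosa,Urotricha globosa,Ciliophora,a-b,"Ba, Al, Fl",8.33,8.33,0,16.67,16.67,0,0.02,0.06,0,0.22,0.29,0,8.33,0.1,,TRUE,FALSE
vorticella_convallaria,Vorticella convallaria,Ciliophora,a,Ba,41.67,208.33,183.33,100,0,50,0.42,2.13,1.9,1.19,0,0.68,97.22,1.05,II;III;IV,TRUE,FALSE
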