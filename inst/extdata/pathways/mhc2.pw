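# MHC class II antigen processing and presentation, 7 reaction modules.
# Gene lists are representative placeholders; apply a curated module->gene
# export with set_module_genes() for full lists.
pathway mhc2
module uptake "Antigen uptake" genes=MRC1,CD36,FCGR1A
module proc "Endosomal/lysosomal processing" genes=CTSS,CTSB,CTSL,CTSD,LGMN
module bio "MHC-II biosynthesis (ER)" genes=HLA-DRA,HLA-DRB1,HLA-DPA1,HLA-DQA1,CD74
module erg2 "ER-to-Golgi transport" genes=SAR1B,SEC23B
module g2e "Golgi-to-endosome transport" genes=AP1B1,AP1M1,RAB7A
module assoc "Antigen association with MHC-II" genes=HLA-DMA,HLA-DMB,HLA-DOA
module surf "Surface expression of peptide-MHC-II" genes=MARCHF1,RAB8B
intermediate c_intern "Internalized protein" gamma=1
intermediate c_pep2 "Endosomal peptides" gamma=1
intermediate c_mhc2_er "MHC-II complex (ER)" gamma=1
intermediate c_mhc2_golgi "MHC-II complex (Golgi)" gamma=1
intermediate c_mhc2_endo "MHC-II complex (endosome)" gamma=1
intermediate c_loaded2 "Peptide-MHC-II complex" gamma=1
edge uptake -> c_intern
edge c_intern -> proc
edge proc -> c_pep2
edge c_pep2 -> assoc
edge bio -> c_mhc2_er
edge c_mhc2_er -> erg2
edge erg2 -> c_mhc2_golgi
edge c_mhc2_golgi -> g2e
edge g2e -> c_mhc2_endo
edge c_mhc2_endo -> assoc
edge assoc -> c_loaded2
edge c_loaded2 -> surf
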