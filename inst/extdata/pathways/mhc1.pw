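# MHC class I antigen processing and presentation, 8 reaction modules.
# Gene lists are representative placeholders; apply a curated module->gene
# export with set_module_genes() for full lists.
pathway mhc1
module ub "Ubiquitination" genes=UBB,UBC,UBA52,UBE2L3
module deub "De-ubiquitination branch" genes=USP14,UCHL5,PSMD14
module prot "Proteasomal degradation" genes=PSMB8,PSMB9,PSMB10,PSMA7
module tap "TAP peptide transport" genes=TAP1,TAP2,ERAP1
module plc "Peptide-loading-complex assembly" genes=TAPBP,CALR,PDIA3,B2M,HLA-A,HLA-B,HLA-C
module erg "ER-to-Golgi transit" genes=SAR1A,SEC13,SEC23A,SEC24A
module gm "Golgi-to-membrane exocytosis" genes=RAB8A,STX4,SNAP23
module recyc "Surface-complex recycling" genes=MAL2,RAB11A,EEA1
intermediate c_ub "Ubiquitinated protein" gamma=1
intermediate c_pep "Cytosolic peptides" gamma=1
intermediate c_erpep "ER-lumenal peptides" gamma=1
intermediate c_loaded "Loaded MHC-I complex (ER)" gamma=1
intermediate c_golgi "MHC-I complex (Golgi)" gamma=1
intermediate c_surface "Surface MHC-I complex" gamma=1
edge ub -> c_ub
edge c_ub -> prot
edge c_ub -> deub
edge prot -> c_pep
edge c_pep -> tap
edge tap -> c_erpep
edge c_erpep -> plc
edge plc -> c_loaded
edge c_loaded -> erg
edge erg -> c_golgi
edge c_golgi -> gm
edge gm -> c_surface
edge c_surface -> recyc
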