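# SYNTHETIC stand-in for a curated MHC-I module->gene export.
# Gene identifiers are placeholders, not curated gene symbols.
module_id	gene_id
ub	SYN1_UB_001
ub	SYN1_UB_002
ub	SYN1_UB_003
ub	SYN1_UB_004
ub	SYN1_UB_005
ub	SYN1_UB_006
ub	SYN1_UB_007
ub	SYN1_UB_008
ub	SYN1_UB_009
ub	SYN1_UB_010
ub	SYN1_UB_011
ub	SYN1_UB_012
ub	SYN1_UB_013
ub	SYN1_UB_014
ub	SYN1_UB_015
ub	SYN1_UB_016
ub	SYN1_UB_017
ub	SYN1_UB_018
ub	SYN1_UB_019
ub	SYN1_UB_020
ub	SYN1_UB_021
ub	SYN1_UB_022
ub	SYN1_UB_023
ub	SYN1_UB_024
ub	SYN1_UB_025
ub	SYN1_UB_026
ub	SYN1_UB_027
ub	SYN1_UB_028
ub	SYN1_UB_029
ub	SYN1_UB_030
ub	SYN1_UB_031
ub	SYN1_UB_032
ub	SYN1_UB_033
ub	SYN1_UB_034
ub	SYN1_UB_035
ub	SYN1_UB_036
ub	SYN1_UB_037
ub	SYN1_UB_038
ub	SYN1_UB_039
ub	SYN1_UB_040
deub	SYN1_DEUB_001
deub	SYN1_DEUB_002
deub	SYN1_DEUB_003
deub	SYN1_DEUB_004
deub	SYN1_DEUB_005
deub	SYN1_DEUB_006
deub	SYN1_DEUB_007
deub	SYN1_DEUB_008
deub	SYN1_DEUB_009
deub	SYN1_DEUB_010
deub	SYN1_DEUB_011
deub	SYN1_DEUB_012
deub	SYN1_DEUB_013
deub	SYN1_DEUB_014
deub	SYN1_DEUB_015
deub	SYN1_DEUB_016
deub	SYN1_DEUB_017
deub	SYN1_DEUB_018
prot	SYN1_PROT_001
prot	SYN1_PROT_002
prot	SYN1_PROT_003
prot	SYN1_PROT_004
prot	SYN1_PROT_005
prot	SYN1_PROT_006
prot	SYN1_PROT_007
prot	SYN1_PROT_008
prot	SYN1_PROT_009
prot	SYN1_PROT_010
prot	SYN1_PROT_011
prot	SYN1_PROT_012
prot	SYN1_PROT_013
prot	SYN1_PROT_014
prot	SYN1_PROT_015
prot	SYN1_PROT_016
prot	SYN1_PROT_017
prot	SYN1_PROT_018
prot	SYN1_PROT_019
prot	SYN1_PROT_020
prot	SYN1_PROT_021
prot	SYN1_PROT_022
prot	SYN1_PROT_023
prot	SYN1_PROT_024
prot	SYN1_PROT_025
prot	SYN1_PROT_026
prot	SYN1_PROT_027
prot	SYN1_PROT_028
prot	SYN1_PROT_029
prot	SYN1_PROT_030
prot	SYN1_PROT_031
prot	SYN1_PROT_032
prot	SYN1_PROT_033
prot	SYN1_PROT_034
prot	SYN1_PROT_035
prot	SYN1_PROT_036
prot	SYN1_PROT_037
prot	SYN1_PROT_038
prot	SYN1_PROT_039
prot	SYN1_PROT_040
prot	SYN1_PROT_041
prot	SYN1_PROT_042
prot	SYN1_PROT_043
prot	SYN1_PROT_044
prot	SYN1_PROT_045
prot	SYN1_PROT_046
prot	SYN1_PROT_047
prot	SYN1_PROT_048
prot	SYN1_PROT_049
prot	SYN1_PROT_050
prot	SYN1_PROT_051
prot	SYN1_PROT_052
tap	SYN1_TAP_001
tap	SYN1_TAP_002
tap	SYN1_TAP_003
tap	SYN1_TAP_004
tap	SYN1_TAP_005
tap	SYN1_TAP_006
tap	SYN1_TAP_007
tap	SYN1_TAP_008
tap	SYN1_TAP_009
tap	SYN1_TAP_010
tap	SYN1_TAP_011
tap	SYN1_TAP_012
plc	SYN1_PLC_001
plc	SYN1_PLC_002
plc	SYN1_PLC_003
plc	SYN1_PLC_004
plc	SYN1_PLC_005
plc	SYN1_PLC_006
plc	SYN1_PLC_007
plc	SYN1_PLC_008
plc	SYN1_PLC_009
plc	SYN1_PLC_010
plc	SYN1_PLC_011
plc	SYN1_PLC_012
plc	SYN1_PLC_013
plc	SYN1_PLC_014
plc	SYN1_PLC_015
plc	SYN1_PLC_016
plc	SYN1_PLC_017
plc	SYN1_PLC_018
plc	SYN1_PLC_019
plc	SYN1_PLC_020
plc	SYN1_PLC_021
plc	SYN1_PLC_022
plc	SYN1_PLC_023
plc	SYN1_PLC_024
plc	SYN1_PLC_025
plc	SYN1_PLC_026
plc	SYN1_PLC_027
plc	SYN1_PLC_028
plc	SYN1_PLC_029
plc	SYN1_PLC_030
plc	SYN1_PLC_031
plc	SYN1_PLC_032
plc	SYN1_PLC_033
plc	SYN1_PLC_034
plc	SYN1_PLC_035
plc	SYN1_PLC_036
plc	SYN1_PLC_037
plc	SYN1_PLC_038
erg	SYN1_ERG_001
erg	SYN1_ERG_002
erg	SYN1_ERG_003
erg	SYN1_ERG_004
erg	SYN1_ERG_005
erg	SYN1_ERG_006
erg	SYN1_ERG_007
erg	SYN1_ERG_008
erg	SYN1_ERG_009
erg	SYN1_ERG_010
erg	SYN1_ERG_011
erg	SYN1_ERG_012
erg	SYN1_ERG_013
erg	SYN1_ERG_014
erg	SYN1_ERG_015
erg	SYN1_ERG_016
erg	SYN1_ERG_017
erg	SYN1_ERG_018
erg	SYN1_ERG_019
erg	SYN1_ERG_020
erg	SYN1_ERG_021
erg	SYN1_ERG_022
erg	SYN1_ERG_023
erg	SYN1_ERG_024
erg	SYN1_ERG_025
erg	SYN1_ERG_026
erg	SYN1_ERG_027
erg	SYN1_ERG_028
erg	SYN1_ERG_029
erg	SYN1_ERG_030
erg	SYN1_ERG_031
erg	SYN1_ERG_032
erg	SYN1_ERG_033
erg	SYN1_ERG_034
erg	SYN1_ERG_035
erg	SYN1_ERG_036
erg	SYN1_ERG_037
erg	SYN1_ERG_038
erg	SYN1_ERG_039
erg	SYN1_ERG_040
erg	SYN1_ERG_041
erg	SYN1_ERG_042
erg	SYN1_ERG_043
erg	SYN1_ERG_044
gm	SYN1_GM_001
gm	SYN1_GM_002
gm	SYN1_GM_003
gm	SYN1_GM_004
gm	SYN1_GM_005
gm	SYN1_GM_006
gm	SYN1_GM_007
gm	SYN1_GM_008
gm	SYN1_GM_009
gm	SYN1_GM_010
gm	SYN1_GM_011
gm	SYN1_GM_012
gm	SYN1_GM_013
gm	SYN1_GM_014
gm	SYN1_GM_015
gm	SYN1_GM_016
gm	SYN1_GM_017
gm	SYN1_GM_018
gm	SYN1_GM_019
gm	SYN1_GM_020
gm	SYN1_GM_021
gm	SYN1_GM_022
gm	SYN1_GM_023
gm	SYN1_GM_024
gm	SYN1_GM_025
gm	SYN1_GM_026
gm	SYN1_GM_027
gm	SYN1_GM_028
gm	SYN1_GM_029
gm	SYN1_GM_030
gm	SYN1_GM_031
gm	SYN1_GM_032
gm	SYN1_GM_033
gm	SYN1_GM_034
gm	SYN1_GM_035
gm	SYN1_GM_036
gm	SYN1_GM_037
gm	SYN1_GM_038
gm	SYN1_GM_039
gm	SYN1_GM_040
gm	SYN1_GM_041
gm	SYN1_GM_042
gm	SYN1_GM_043
gm	SYN1_GM_044
gm	SYN1_GM_045
gm	SYN1_GM_046
recyc	SYN1_RECYC_001
recyc	SYN1_RECYC_002
recyc	SYN1_RECYC_003
recyc	SYN1_RECYC_004
recyc	SYN1_RECYC_005
recyc	SYN1_RECYC_006
recyc	SYN1_RECYC_007
recyc	SYN1_RECYC_008
recyc	SYN1_RECYC_009
recyc	SYN1_RECYC_010
recyc	SYN1_RECYC_011
recyc	SYN1_RECYC_012
recyc	SYN1_RECYC_013
recyc	SYN1_RECYC_014
recyc	SYN1_RECYC_015
recyc	SYN1_RECYC_016
recyc	SYN1_RECYC_017
recyc	SYN1_RECYC_018
recyc	SYN1_RECYC_019
recyc	SYN1_RECYC_020
recyc	SYN1_RECYC_021
recyc	SYN1_RECYC_022
recyc	SYN1_RECYC_023
recyc	SYN1_RECYC_024
recyc	SYN1_RECYC_025
recyc	SYN1_RECYC_026
recyc	SYN1_RECYC_027
recyc	SYN1_RECYC_028
recyc	SYN1_RECYC_029
recyc	SYN1_RECYC_030
recyc	SYN1_RECYC_031
recyc	SYN1_RECYC_032
recyc	SYN1_RECYC_033
recyc	SYN1_RECYC_034
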