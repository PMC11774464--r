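# SYNTHETIC stand-in for a curated MHC-II module->gene export.
# Gene identifiers are placeholders, not curated gene symbols.
module_id	gene_id
uptake	SYN2_UPTAKE_001
uptake	SYN2_UPTAKE_002
uptake	SYN2_UPTAKE_003
uptake	SYN2_UPTAKE_004
uptake	SYN2_UPTAKE_005
uptake	SYN2_UPTAKE_006
uptake	SYN2_UPTAKE_007
uptake	SYN2_UPTAKE_008
uptake	SYN2_UPTAKE_009
uptake	SYN2_UPTAKE_010
uptake	SYN2_UPTAKE_011
uptake	SYN2_UPTAKE_012
uptake	SYN2_UPTAKE_013
uptake	SYN2_UPTAKE_014
uptake	SYN2_UPTAKE_015
uptake	SYN2_UPTAKE_016
uptake	SYN2_UPTAKE_017
uptake	SYN2_UPTAKE_018
uptake	SYN2_UPTAKE_019
uptake	SYN2_UPTAKE_020
uptake	SYN2_UPTAKE_021
uptake	SYN2_UPTAKE_022
uptake	SYN2_UPTAKE_023
uptake	SYN2_UPTAKE_024
proc	SYN2_PROC_001
proc	SYN2_PROC_002
proc	SYN2_PROC_003
proc	SYN2_PROC_004
proc	SYN2_PROC_005
proc	SYN2_PROC_006
proc	SYN2_PROC_007
proc	SYN2_PROC_008
proc	SYN2_PROC_009
proc	SYN2_PROC_010
proc	SYN2_PROC_011
proc	SYN2_PROC_012
proc	SYN2_PROC_013
proc	SYN2_PROC_014
proc	SYN2_PROC_015
proc	SYN2_PROC_016
proc	SYN2_PROC_017
proc	SYN2_PROC_018
proc	SYN2_PROC_019
proc	SYN2_PROC_020
proc	SYN2_PROC_021
proc	SYN2_PROC_022
proc	SYN2_PROC_023
proc	SYN2_PROC_024
proc	SYN2_PROC_025
proc	SYN2_PROC_026
bio	SYN2_BIO_001
bio	SYN2_BIO_002
bio	SYN2_BIO_003
bio	SYN2_BIO_004
bio	SYN2_BIO_005
bio	SYN2_BIO_006
bio	SYN2_BIO_007
bio	SYN2_BIO_008
bio	SYN2_BIO_009
bio	SYN2_BIO_010
bio	SYN2_BIO_011
bio	SYN2_BIO_012
bio	SYN2_BIO_013
bio	SYN2_BIO_014
bio	SYN2_BIO_015
bio	SYN2_BIO_016
bio	SYN2_BIO_017
bio	SYN2_BIO_018
bio	SYN2_BIO_019
bio	SYN2_BIO_020
bio	SYN2_BIO_021
bio	SYN2_BIO_022
erg2	SYN2_ERG2_001
erg2	SYN2_ERG2_002
erg2	SYN2_ERG2_003
erg2	SYN2_ERG2_004
erg2	SYN2_ERG2_005
erg2	SYN2_ERG2_006
erg2	SYN2_ERG2_007
erg2	SYN2_ERG2_008
erg2	SYN2_ERG2_009
erg2	SYN2_ERG2_010
erg2	SYN2_ERG2_011
erg2	SYN2_ERG2_012
g2e	SYN2_G2E_001
g2e	SYN2_G2E_002
g2e	SYN2_G2E_003
g2e	SYN2_G2E_004
g2e	SYN2_G2E_005
g2e	SYN2_G2E_006
g2e	SYN2_G2E_007
g2e	SYN2_G2E_008
g2e	SYN2_G2E_009
g2e	SYN2_G2E_010
g2e	SYN2_G2E_011
g2e	SYN2_G2E_012
assoc	SYN2_ASSOC_001
assoc	SYN2_ASSOC_002
assoc	SYN2_ASSOC_003
assoc	SYN2_ASSOC_004
assoc	SYN2_ASSOC_005
assoc	SYN2_ASSOC_006
assoc	SYN2_ASSOC_007
assoc	SYN2_ASSOC_008
assoc	SYN2_ASSOC_009
assoc	SYN2_ASSOC_010
assoc	SYN2_ASSOC_011
assoc	SYN2_ASSOC_012
assoc	SYN2_ASSOC_013
assoc	SYN2_ASSOC_014
surf	SYN2_SURF_001
surf	SYN2_SURF_002
surf	SYN2_SURF_003
surf	SYN2_SURF_004
surf	SYN2_SURF_005
surf	SYN2_SURF_006
surf	SYN2_SURF_007
surf	SYN2_SURF_008
surf	SYN2_SURF_009
surf	SYN2_SURF_010
surf	SYN2_SURF_011
surf	SYN2_SURF_012
surf	SYN2_SURF_013
surf	SYN2_SURF_014
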