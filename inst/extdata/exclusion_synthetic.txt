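# Synthetic stand-in for the curated crystallization-additive exclusion list
# (the full manually curated list of 465 component IDs ships with the source
# database; drop a replacement file in via read_exclusion_list(path)).
# One chemical component ID per line; '#' starts a comment.
GOL
EDO
PEG
PG4
PGE
1PE
P6G
MPD
DMS
ACT
ACY
FMT
EOH
IPA
MOH
BME
MRD
TRS
EPE
MES
BIS
CIT
FLC
TLA
TAR
SO4
PO4
NO3
AZI
BCT
CO3
SCN
CAC
IMD
GAI
UNX
DOD
NH4
CL
BR
IOD
F
NA
K
LI
CS
MG
CA
SR
BA
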