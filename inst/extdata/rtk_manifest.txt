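# 58 human receptor tyrosine kinases, by subfamily (gene symbols)
# ErbB
EGFR
ERBB2
ERBB3
ERBB4
# Insulin receptor
INSR
IGF1R
INSRR
# PDGFR
PDGFRA
PDGFRB
KIT
CSF1R
FLT3
# VEGFR
FLT1
KDR
FLT4
# FGFR
FGFR1
FGFR2
FGFR3
FGFR4
# PTK7/CCK4
PTK7
# Trk
NTRK1
NTRK2
NTRK3
# Ror
ROR1
ROR2
# MuSK
MUSK
# Met
MET
MST1R
# Axl
AXL
MERTK
TYRO3
# Tie
TIE1
TEK
# Eph
EPHA1
EPHA2
EPHA3
EPHA4
EPHA5
EPHA6
EPHA7
EPHA8
EPHA10
EPHB1
EPHB2
EPHB3
EPHB4
EPHB6
# Ret
RET
# Ryk
RYK
# DDR
DDR1
DDR2
# Ros
ROS1
# LMR
AATK
LMTK2
LMTK3
# ALK
ALK
LTK
# STYK1
STYK1
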