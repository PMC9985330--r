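# Curated human housekeeping gene symbols used as negative controls for
# RUV-style correction: classical loading controls, glycolytic enzymes,
# ribosomal proteins and core translation/transcription machinery.
ACTB
GAPDH
B2M
HPRT1
TBP
UBC
UBB
PPIA
PPIB
PGK1
RPLP0
RPLP1
RPLP2
GUSB
TFRC
HMBS
SDHA
YWHAZ
POLR2A
RPL3
RPL4
RPL5
RPL6
RPL7
RPL7A
RPL8
RPL9
RPL10
RPL10A
RPL11
RPL12
RPL13
RPL13A
RPL14
RPL15
RPL17
RPL18
RPL18A
RPL19
RPL21
RPL22
RPL23
RPL23A
RPL24
RPL26
RPL27
RPL27A
RPL28
RPL29
RPL30
RPL31
RPL32
RPL34
RPL35
RPL35A
RPL36
RPL37
RPL37A
RPL38
RPL39
RPL41
RPS2
RPS3
RPS3A
RPS4X
RPS5
RPS6
RPS7
RPS8
RPS9
RPS10
RPS11
RPS12
RPS13
RPS14
RPS15
RPS15A
RPS16
RPS17
RPS18
RPS19
RPS20
RPS21
RPS23
RPS24
RPS25
RPS26
RPS27
RPS27A
RPS28
RPS29
RPSA
EEF1A1
EEF1B2
EEF1G
EEF2
EIF1
EIF3A
EIF4A2
EIF4G2
NACA
BTF3
HNRNPA1
HNRNPC
HNRNPK
PABPC1
SRSF3
PTBP1
PCBP1
PCBP2
TUBA1B
TUBB
VIM
ATP5F1A
ATP5F1B
ATP5PO
COX4I1
COX6B1
COX7C
NDUFA4
UQCRH
SLC25A3
VDAC1
PSMA1
PSMA7
PSMB2
PSMB4
PSMC1
PSMD2
CCT3
CCT5
HSP90AA1
HSP90AB1
HSPA8
HSPD1
CANX
CALR
PFN1
CFL1
MYL6
ARPC2
GNB2L1
RACK1
TMBIM6
SF3B1
SNRPD2
PRPF8
LDHA
LDHB
ENO1
ALDOA
TPI1
PKM
GPI
FAU
UBA52
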