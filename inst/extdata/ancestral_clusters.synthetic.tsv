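# Default ancestral angiosperm mitochondrial gene-cluster catalog.
# SYNTHETIC/REPLACEABLE DEFAULT: the three clusters named in the primary
# literature on conifer mitogenome synteny loss (nad3-rps12,
# rpl16-rps3-rps19-rpl2, trnP-sdh3) plus eleven stand-in clusters assembled
# from commonly reported conserved angiosperm mitochondrial syntenies.
# Replace with a study-specific catalog via check_cluster_retention(catalog=).
# Columns: cluster name <TAB> comma-joined ordered gene list.
nad3-rps12	nad3,rps12
rpl16-rps3-rps19-rpl2	rpl16,rps3,rps19,rpl2
trnP-sdh3	trnP,sdh3
rrn18-rrn5	rrn18,rrn5
nad4L-atp4	nad4L,atp4
sdh4-cox3	sdh4,cox3
rps10-cox1	rps10,cox1
ccmFn-rps1	ccmFn,rps1
rps13-nad1	rps13,nad1
atp8-cox2	atp8,cox2
nad6-nad9	nad6,nad9
trnY-trnE	trnY,trnE
rps4-nad2	rps4,nad2
ccmB-ccmC	ccmB,ccmC
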