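# coliflux network format v1
# po_ratio: 2
id	equation	role	reversible	lumped_from
PTS	1 GLC.e + 1 PEP -> 1 G6P + 1 PYR	measured_inflow	FALSE	ptsGHI,crr
OUT_ACE	1 ACE -> 1 ACE.e	outflow	TRUE	
OUT_LAC	1 PYR + 1 NADH -> 1 LAC.e	outflow	FALSE	ldhA
OUT_CBASP	1 CBASP -> 1 CBASP.e	outflow	FALSE	
OUT_DHO	1 DHO -> 1 DHO.e	outflow	FALSE	
OUT_ORO	1 ORO -> 1 ORO.e	outflow	FALSE	
OUT_NAA	1 ACCOA + 1 ASP -> 1 NAA.e	outflow	FALSE	yjgM
OUT_VPROD	1 OAA -> 1 VPROD.e	outflow	FALSE	
PGI	1 G6P -> 1 F6P	dependent	TRUE	pgi
PFK	1 F6P + 1 ATP -> 2 GAP	dependent	FALSE	pfkA,fbaA,tpiA
GAPD	1 GAP -> 1 PGA + 1 ATP + 1 NADH	dependent	FALSE	gapA,pgk
ENO	1 PGA -> 1 PEP	dependent	TRUE	gpmA,eno
PYK	1 PEP -> 1 PYR + 1 ATP	dependent	FALSE	pykA,pykF
PDH	1 PYR -> 1 ACCOA + 1 CO2 + 1 NADH	dependent	FALSE	aceEF-lpd
ZWF	1 G6P -> 1 R5P + 1 CO2 + 2 NADPH	dependent	FALSE	zwf,pgl,gnd,rpiA
TKT1	3 R5P -> 2 F6P + 1 GAP	dependent	TRUE	tktA,talB
TKT2	2 R5P -> 1 F6P + 1 E4P	dependent	TRUE	tktB,talA
PPC	1 PEP + 1 CO2 -> 1 OAA	dependent	TRUE	ppc,pck
CS	1 ACCOA + 1 OAA -> 1 ICT	dependent	FALSE	gltA,acnB
ICD	1 ICT -> 1 AKG + 1 CO2 + 1 NADPH	dependent	FALSE	icd
AKGDH	1 AKG -> 1 MAL + 1 CO2 + 1 ATP + 2 NADH	dependent	FALSE	sucAB-lpd,sucCD,sdhABCD,fumA
MDH	1 MAL -> 1 OAA + 1 NADH	dependent	TRUE	mdh
GLX	1 ICT + 1 ACCOA -> 2 MAL + 1 NADH	dependent	FALSE	aceA,aceB,sdhABCD,fumA
PTA	1 ACCOA -> 1 ACE + 1 ATP	dependent	FALSE	pta,ackA
ACS	1 ACE + 2 ATP -> 1 ACCOA	dependent	FALSE	acs
ASPC	1 OAA + 1 NADPH -> 1 ASP	dependent	FALSE	aspC,gdhA
PYRB	1 ASP + 1 CO2 + 2 ATP -> 1 CBASP	dependent	FALSE	carAB,pyrB
PYRC	1 CBASP -> 1 DHO	dependent	TRUE	pyrC
PYRD	1 DHO -> 1 ORO + 1 NADH	dependent	FALSE	pyrD
OXPHOS	1 NADH -> 2 ATP	dependent	FALSE	nuo,cyo,atp
ATPSPILL	1 ATP ->	dependent	FALSE	
OUT_CO2	1 CO2 -> 1 CO2.e	dependent	FALSE	
D_PROT_ALA	1 PYR + 1 NADPH -> 3 BIO.C	biomass_drain	FALSE	
D_PROT_SER	1 PGA + 1 NADPH -> 3 BIO.C	biomass_drain	FALSE	
D_PROT_ASP	1 ASP + 2 NADPH + 2 ATP -> 4 BIO.C	biomass_drain	FALSE	
D_PROT_GLU	1 AKG + 2 NADPH + 1 ATP -> 5 BIO.C	biomass_drain	FALSE	
D_PROT_ARO	1 E4P + 2 PEP + 2 NADPH + 1 ATP -> 10 BIO.C	biomass_drain	FALSE	
D_PROT_HIS	1 R5P + 2 ATP -> 5 BIO.C + 1 NADH	biomass_drain	FALSE	
D_RNA_PUR	1 R5P + 2 PGA + 1 ASP + 4 ATP -> 10 BIO.C + 1 MAL + 1 CO2 + 1 NADH	biomass_drain	FALSE	
D_RNA_PYR	1 ORO + 1 R5P + 1 ATP -> 9 BIO.C + 1 CO2	biomass_drain	FALSE	
D_DNA_PUR	1 R5P + 2 PGA + 1 ASP + 4 ATP + 1 NADPH -> 10 BIO.C + 1 MAL + 1 CO2 + 1 NADH	biomass_drain	FALSE	
D_DNA_PYR	1 ORO + 1 R5P + 1 ATP + 1 NADPH -> 9 BIO.C + 1 CO2	biomass_drain	FALSE	
D_LIPID	8 ACCOA + 0.5 GAP + 14 NADPH + 7 ATP -> 17.5 BIO.C	biomass_drain	FALSE	
D_LPS	2 G6P + 1 F6P + 1 ACCOA + 2 ATP -> 20 BIO.C	biomass_drain	FALSE	
D_MUREIN	2 F6P + 1 PEP + 1 PYR + 1 ASP + 4 ATP + 1 NADPH -> 22 BIO.C	biomass_drain	FALSE	
D_GLYCOGEN	1 G6P + 1 ATP -> 6 BIO.C	biomass_drain	FALSE	
D_SOLUBLE	1 G6P + 2 ATP -> 6 BIO.C	biomass_drain	FALSE	
D_ATP	1 ATP ->	biomass_drain	FALSE	
D_NADPH	1 NADPH ->	biomass_drain	FALSE	
D_NADH	-> 1 NADH	biomass_drain	FALSE	
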