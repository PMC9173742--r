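name,full_name,locality,midline,vta_subnucleus,serotonergic_group
cortex,Anterior cortex,long_range,FALSE,FALSE,none
NAcMed,Nucleus accumbens medial shell,long_range,FALSE,FALSE,none
NAcCore,Nucleus accumbens core,long_range,FALSE,FALSE,none
NAcLat,Nucleus accumbens lateral shell,long_range,FALSE,FALSE,none
DStr,Dorsal striatum,long_range,FALSE,FALSE,none
septum,Septum,long_range,FALSE,FALSE,none
BNST,Bed nucleus of the stria terminalis,long_range,FALSE,FALSE,none
PO,Preoptic nucleus,long_range,FALSE,FALSE,none
PVH,Paraventricular hypothalamus,long_range,FALSE,FALSE,none
LH,Lateral hypothalamus,long_range,FALSE,FALSE,none
ZI,Zona incerta,long_range,FALSE,FALSE,none
EAM,Extended amygdala,long_range,FALSE,FALSE,none
CeA,Central amygdala,long_range,FALSE,FALSE,none
EP,Entopeduncular nucleus,long_range,FALSE,FALSE,none
GPe,Globus pallidus external segment,long_range,FALSE,FALSE,none
MHb,Medial habenula,long_range,FALSE,FALSE,none
LHb,Lateral habenula,long_range,FALSE,FALSE,none
DR,Dorsal raphe,long_range,TRUE,FALSE,B7
LDT,Laterodorsal tegmentum,long_range,FALSE,FALSE,none
PBN,Parabrachial nucleus,long_range,FALSE,FALSE,none
DCN,Deep cerebellar nuclei,long_range,FALSE,FALSE,none
LC,Locus coeruleus,long_range,FALSE,FALSE,none
PBP,VTA parabrachial pigmented nucleus,local,FALSE,TRUE,none
PN,VTA paranigral nucleus,local,FALSE,TRUE,none
IF,VTA interfascicular nucleus,local,FALSE,TRUE,none
Rli,Rostrolinear nucleus,local,FALSE,TRUE,none
SNc,Substantia nigra pars compacta,local,FALSE,FALSE,none
SNr,Substantia nigra pars reticulata,local,FALSE,FALSE,none
SNl,Substantia nigra pars lateralis,local,FALSE,FALSE,none
RRF,Retrorubral field,local,FALSE,FALSE,none
IPN,Interpeduncular nucleus,local,FALSE,FALSE,none
mRT,Midbrain reticular nucleus,local,FALSE,FALSE,B6
PAG,Periaqueductal gray,local,FALSE,FALSE,none
PnO,Pontine reticular nucleus oral part,local,FALSE,FALSE,B5
PnC,Pontine reticular nucleus caudal part,local,FALSE,FALSE,none
PPTg,Pedunculopontine tegmental nucleus,local,FALSE,FALSE,none
SPTg,Subpeduncular tegmental nucleus,local,FALSE,FALSE,none
SubB,Subbrachial nucleus,local,FALSE,FALSE,none
InC,Interstitial nucleus of Cajal,local,FALSE,FALSE,none
RI,Rostral interstitial nucleus,local,FALSE,FALSE,none
PT,Paratrochlear nucleus,local,FALSE,FALSE,none
MnR,Median raphe,local,TRUE,FALSE,B8
PMnR,Paramedian raphe nucleus,local,FALSE,FALSE,B9
RMg,Raphe magnus,local,TRUE,FALSE,B3
SuM,Supramammillary nucleus,local,FALSE,FALSE,none
SuMx,Supramammillary decussation,local,FALSE,FALSE,none
MM,Medial mammillary nucleus,local,FALSE,FALSE,none
RtTg,Reticulotegmental nucleus,local,FALSE,FALSE,none
ATg,Anterior tegmental nucleus,local,FALSE,FALSE,none
VTg,Ventral tegmental nucleus,local,FALSE,FALSE,none
SC,Superior colliculus,local,FALSE,FALSE,none
IC,Inferior colliculus,local,FALSE,FALSE,none
RPC,Red nucleus parvocellular part,local,FALSE,FALSE,none
PSth,Parasubthalamic nucleus,local,FALSE,FALSE,none
MiTg,Microcellular tegmental nucleus,local,FALSE,FALSE,none
DLL,Dorsal nucleus of the lateral lemniscus,local,FALSE,FALSE,none
MPL,Medial paralemniscal nucleus,local,FALSE,FALSE,none
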