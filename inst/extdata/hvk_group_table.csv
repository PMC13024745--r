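name,F_d,F_p,E_h,V
CH3,420,0,0,33.5
CH2,270,0,0,16.1
CH_OH,290,500,20000,9.0
OH,210,500,20000,10.0
NH2,280,0,8400,19.2
NH,160,210,3100,4.5
O_ether,100,400,3000,3.8
CO_ketone,290,770,2000,10.8
COO_ester,390,490,7000,18.0
COOH,530,420,10000,28.5
CH_aromatic,265,0,0,15.1
C6H5_phenyl,1430,110,0,71.4
C6H4_phenylene,1270,110,0,52.4
C6H3_benzene_trisub,1110,110,0,33.4
C6H2_benzene_tetrasub,950,110,0,14.4
CH2_olefin,400,0,0,28.5
CH_olefin,200,0,0,13.5
F,220,220,0,18.0
Cl,450,550,400,24.0
CN,430,1100,2500,24.0
NO2,500,1070,1500,24.0
S_sulfide,440,0,0,12.0
SO_sulfoxide,472,1170,7400,15.8
ring_nonaromatic,190,0,0,16.0
ring_methylidene_cyclopentadiene,600,0,0,13.0
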