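# Canonical TLR4-pathway core signalling molecules (starting seed list;
# extend with additional curated members as needed, one symbol per line)
Tlr4
Ticam1
Ticam2
Tirap
Myd88
Traf6
Traf3
Irak1
Ikbke
Ikbkg
Irf7
Nfkb1
Nfkbia
Rela
Fos
Jun
Mapk1
Mapk8
Mapk11
Map3k7
Tab2
Ripk1
Tollip
Cd14
Ly96
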