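category,brazil,nbz,bz5,study_area
EX,5,0,0,5
EW,2,1,1,2
CR,55,6,15,45
EN,157,37,60,134
VU,271,67,90,198
NT,43,9,19,34
LC,747,268,369,663
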