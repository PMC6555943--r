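table,area,source,tp,fp,fn
all,A,google,19,11,13
all,A,osm,15,2,17
all,B,google,58,7,1
all,B,osm,12,0,47
all,C,google,144,57,63
all,C,osm,41,6,166
all,D,google,22,12,11
all,D,osm,21,5,12
no_doctor,A,google,18,11,13
no_doctor,A,osm,15,2,16
no_doctor,B,google,29,3,1
no_doctor,B,osm,10,0,20
no_doctor,C,google,48,21,30
no_doctor,C,osm,36,6,42
no_doctor,D,google,19,9,6
no_doctor,D,osm,21,5,4
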