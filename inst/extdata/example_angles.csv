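surface_id,liquid,angle_deg,replicate
GS,water,24.1,1
GS,water,25.6,2
GS,water,25.3,3
GS,formamide,24.8,1
GS,formamide,28.9,2
GS,formamide,24.3,3
GS,diiodomethane,36.2,1
GS,diiodomethane,40.8,2
GS,diiodomethane,37.0,3
PC,water,77.2,1
PC,water,78.6,2
PC,water,78.2,3
PC,formamide,69.3,1
PC,formamide,70.9,2
PC,formamide,69.8,3
PC,diiodomethane,25.1,1
PC,diiodomethane,26.8,2
PC,diiodomethane,26.1,3
PE,water,96.4,1
PE,water,97.8,2
PE,water,96.8,3
PE,formamide,83.1,1
PE,formamide,84.7,2
PE,formamide,84.2,3
PE,diiodomethane,54.0,1
PE,diiodomethane,55.9,2
PE,diiodomethane,55.1,3
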