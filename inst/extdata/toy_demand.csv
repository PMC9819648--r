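site_id,x,y,population,zone_id
r1,0,0,100,north
r2,1000,0,200,north
r3,2000,0,300,south
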