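origin_id,dest_id,mode,minutes
r1,p1,walking,10
r1,p2,walking,50
r2,p1,walking,20
r2,p2,walking,30
r3,p1,walking,45
r3,p2,walking,15
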