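site_id,x,y,area,score
p1,200,0,10,1
p2,1800,0,20,1
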