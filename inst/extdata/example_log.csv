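player_id,room_id,t,phase
p1,A,0,exploration
p1,B,6,exploration
p1,C,12,exploration
p1,B,18,exploration
p1,D,24,exploration
p1,B,30,exploration
p1,E,36,exploration
p1,B,42,testing
p1,A,48,testing
p2,A,0,exploration
p2,B,6,exploration
p2,E,12,exploration
p2,B,18,exploration
p2,C,24,exploration
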