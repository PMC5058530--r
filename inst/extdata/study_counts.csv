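forest_cover,adults,seedlings,same_landscape,other_landscape,assigned
19,52,27,3,0,3
28,14,11,1,0,1
34,13,5,1,0,1
43,18,26,3,0,3
50,27,51,3,2,5
59,28,41,2,1,3
63,51,70,3,1,4
70,26,26,0,0,0
83,17,14,0,1,1
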