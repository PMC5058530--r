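site_id,centroid_x,centroid_y,forest_cover
L19,15000,-15000,19
L28,-15000,-10000,28
L34,10000,18000,34
L43,0,0,43
L50,5000,0,50
L59,-4400,8980,59
L63,20000,5000,63
L70,22000,5000,70
L83,0,-8000,83
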