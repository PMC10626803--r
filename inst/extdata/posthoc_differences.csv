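analysis,pair,mean_diff
alps_right,CM - HC,0.140
alps_right,CM - EM,0.133
alps_right_minus_left_cm,CM right - left,0.118
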