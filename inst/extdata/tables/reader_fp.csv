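reader_id,fp_pre,fp_increase,fp_reduction,fp_post
R1,7,4,3,8
R2,6,2,0,8
R3,4,2,1,5
R4,8,0,2,6
R5,6,0,0,6
R6,9,0,0,9
R7,9,0,0,9
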