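reader_id,recalled_pre,additional_recalled,ignored_flags
R1,30,17,8
R2,40,10,9
R3,22,6,22
R4,34,5,16
R5,50,3,10
R6,45,2,8
R7,47,2,7
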