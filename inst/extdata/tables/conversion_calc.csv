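reader_id,recalled_pre,additional_recalled,ignored_flags
R1,8,6,3
R2,9,3,5
R3,1,8,8
R4,7,1,9
R5,14,1,2
R6,5,2,10
R7,8,3,6
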