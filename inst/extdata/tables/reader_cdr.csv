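reader_id,years_experience,cdr_pre_pct,cdr_post_pct
R1,3,42,68
R2,3,54,68
R3,42,25,41
R4,5,46,53
R5,6,71,75
R6,3,56,60
R7,19,61,67
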