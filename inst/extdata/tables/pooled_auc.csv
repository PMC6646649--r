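curve,auc
pre,0.7599
post,0.8148
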