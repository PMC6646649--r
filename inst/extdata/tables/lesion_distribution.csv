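lesion_components,count
mass,50
microcalcifications,16
mass;microcalcifications,9
architectural_distortion,5
mass;architectural_distortion,4
asymmetry,3
architectural_distortion;microcalcifications,1
microcalcifications;asymmetry,1
focal_asymmetry,1
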