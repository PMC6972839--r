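subset,n_birds,n_locs
classification,460,3766
validation_within_rsf,NA,4354
validation_outside_rsf,NA,6048
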