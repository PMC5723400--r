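species,dist_shore,cyclone_pr,kd490,sst,dugong
Halodule uninervis,NA,0.572,0.044,0.240,0.370
Halophila ovalis,0.027,0.229,0.130,0.395,0.584
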