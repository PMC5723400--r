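species,label,predictors,AICc,delta_AICc,wi,r2
Halodule uninervis,cyclone.sqrt,cyclone_pr,1.114,0,0.572,0.677
Halodule uninervis,SST.log+dugong,sst;dugong,3.078,1.964,0.214,0.639
Halodule uninervis,dugong,dugong,4.002,2.888,0.135,0.505
Halodule uninervis,KD490.sqrt,kd490,6.239,5.125,0.044,0.515
Halodule uninervis,dugong+SST.log.by.dugong,dugong;sst,7.714,6.6,0.021,0.64
Halodule uninervis,null,,11.378,10.264,0.003,0
Halodule uninervis,SST.log,sst,12.51,11.396,0.002,0.273
Halophila ovalis,SST.log+dugong,sst;dugong,8.525,0,0.315,0.566
Halophila ovalis,cyclone.sqrt,cyclone_pr,9.164,0.638,0.229,0.533
Halophila ovalis,dugong,dugong,9.425,0.9,0.201,0.382
Halophila ovalis,KD490.sqrt,kd490,10.566,2.041,0.113,0.33
Halophila ovalis,dugong+SST.log.by.dugong,dugong;sst,11.59,3.065,0.068,0.624
Halophila ovalis,null,,12.863,4.338,0.036,0
Halophila ovalis,Dist.shore.sqrt+KD490.sqrt,dist_shore;kd490,14.399,5.874,0.017,0.34
Halophila ovalis,SST.log,sst,15.069,6.544,0.012,0.076
Halophila ovalis,Dist.shore.sqrt,dist_shore,15.505,6.98,0.01,0.066
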