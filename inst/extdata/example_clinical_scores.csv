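patient,timepoint,days_post_onset,mrs,nihss,bi,fma_ue
P1,S1,5,2,3,85,62
P1,S2,40,2,2,100,66
P1,S3,82,2,2,100,66
P2,S1,7,3,6,60,35
P2,S2,42,2,1,95,57
P2,S3,105,2,2,95,56
P3,S1,3,4,5,50,58
P3,S2,33,4,6,65,59
P3,S3,92,2,3,100,66
P4,S1,2,2,1,100,66
P4,S2,35,2,1,100,66
P4,S3,107,1,0,100,65
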