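patient,timepoint,volume_mm3
P1,S1,21428
P1,S2,19198
P1,S3,12841
P2,S1,18141
P2,S2,7310
P2,S3,8581
P3,S1,959
P3,S2,441
P3,S3,113
P4,S1,312
P4,S2,265
P4,S3,141
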