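scenario,architecture,grayscale,class,n11,n10,n01,n00,reported_significant,class_size
cross-scanner,ResNet50,Luster,0,13,1,11,13,TRUE,38
cross-scanner,ResNet50,Luster,1,8,16,3,33,TRUE,60
cross-scanner,ResNet50,Luster,2,1,2,5,14,FALSE,22
cross-scanner,ResNet50,ACSRM,0,7,7,0,24,TRUE,38
cross-scanner,ResNet50,ACSRM,1,8,16,11,25,FALSE,60
cross-scanner,ResNet50,ACSRM,2,3,0,14,5,TRUE,22
cross-scanner,Swin-B,ACSRM,0,11,3,0,24,FALSE,38
cross-scanner,Swin-B,ACSRM,1,17,7,4,32,FALSE,60
cross-scanner,Swin-B,ACSRM,2,3,0,11,8,TRUE,22
cross-center,VGG19,ACSRM,all,247,79,97,111,FALSE,NA
cross-center,Swin-B,Luster,all,262,64,147,61,TRUE,NA
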