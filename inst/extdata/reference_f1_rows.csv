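source,architecture,format,precision,recall,f1
Radboud,Swin-B,Luster,0.69,0.91,0.78
Radboud,Swin-B,RGB,0.62,0.42,0.50
Radboud,VGG19,ACSRM,0.71,0.41,0.52
Radboud,VGG19,RGB,0.45,0.06,0.11
Karolinska,VGG19,RGB,0.73,0.65,0.69
Karolinska,VGG19,ACSRM,0.71,0.71,0.71
Karolinska,Swin-B,RGB,0.68,0.71,0.69
Karolinska,Swin-B,Luster,0.71,0.69,0.70
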