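constituent,min,mean,max,sd,sel
NDF,76,87,97,4.5,0.45
IVTD,21,46,64,13,0.57
NDFD,40,70,93,13,1.34
ADF,18,30,38,5.8,0.74
ADL,1.5,3.7,7.2,1.2,0.29
CP,13,20,33,4.8,0.21
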