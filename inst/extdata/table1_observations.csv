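patient_id,mi,artery,treated,matched
case_I,Y,RCA,1,1
case_I,Y,LAD,0,NA
case_I,Y,LCX,1,1
case_II,Y,RCA,0,NA
case_II,Y,LAD,1,1
case_II,Y,LCX,1,1
case_III,N,RCA,0,NA
case_III,N,LAD,0,NA
case_III,N,LCX,1,1
case_IV,N,RCA,1,1
case_IV,N,LAD,0,NA
case_V,Y,RCA,0,NA
case_V,Y,LAD,1,0
case_V,Y,LCX,0,NA
case_VI,Y,RCA,0,NA
case_VI,Y,LAD,1,0
case_VI,Y,LCX,0,NA
case_VII,N,RCA,1,1
case_VII,N,LAD,0,NA
case_VII,N,LCX,0,NA
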