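patient_id,artery,min_ssi
case_I,RCA,546
case_I,LAD,581
case_I,LCX,543
case_II,RCA,412
case_II,LAD,329
case_II,LCX,239
case_III,RCA,792
case_III,LAD,874
case_III,LCX,429
case_IV,RCA,729
case_IV,LAD,793
case_IV,LCX,NA
case_V,RCA,468
case_V,LAD,755
case_V,LCX,877
case_VI,RCA,520
case_VI,LAD,980
case_VI,LCX,532
case_VII,RCA,1171
case_VII,LAD,1238
case_VII,LCX,1400
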