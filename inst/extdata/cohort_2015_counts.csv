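stratifier,category,count
gender,male,277641
gender,female,238207
age,0-9,657
age,10-19,575
age,20-29,1465
age,30-39,5558
age,40-49,24243
age,50-59,78878
age,60-69,128542
age,70-79,178504
age,80+,97426
disposition,inpatient,129513
disposition,outpatient,472371
facility,tertiary,187263
facility,general,232450
facility,hospital,102535
facility,clinic,63863
facility,public_health,1833
subtype,ischemic,463147
subtype,hemorrhagic,52701
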