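label,ischemic,hemorrhagic,stroke
inpatient,1378782,519458,1898241
outpatient,99382,14903,114285
noncovered,263113,91375,354489
medication,335280,45409,380689
assistive,122270,13913,136183
transportation,57387,8924,66312
caregiver,242573,75720,318293
mortality_loss,881203,2521126,3402329
morbidity_loss,607442,194562,802005
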