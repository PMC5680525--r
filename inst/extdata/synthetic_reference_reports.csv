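adr_concept,report_count
anxiety,62
overdose,55
paranoia,49
headache,44
cough,41
pain,9
depression,7
withdrawal,5
seizure,4
hallucination,3
nausea,2
emesis,2
fatigue,1
insomnia,1
dizziness,1
hyperhidrosis,1
agitation,0
drowsiness,0
appetite,0
syncope,0
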