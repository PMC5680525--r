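concept_id,kind,synonym
anxiety,adr,anxiety
anxiety,adr,anxious
anxiety,adr,panic attack
cough,adr,cough
cough,adr,coughing
headache,adr,headache
headache,adr,head ache
headache,adr,migraine
nausea,adr,nausea
nausea,adr,feeling sick
emesis,adr,vomiting
emesis,adr,throwing up
emesis,adr,emesis
paranoia,adr,paranoia
paranoia,adr,paranoid
hallucination,adr,hallucination
hallucination,adr,hallucinations
hallucination,adr,seeing things
depression,adr,depression
depression,adr,depressed
overdose,adr,overdose
overdose,adr,overdosed
withdrawal,adr,withdrawal
seizure,adr,seizure
seizure,adr,seizures
pain,adr,pain
abdominal pain,adr,stomach ache
abdominal pain,adr,abdominal pain
fatigue,adr,fatigue
fatigue,adr,exhausted
insomnia,adr,insomnia
insomnia,adr,cant sleep
dizziness,adr,dizziness
dizziness,adr,dizzy
hyperhidrosis,adr,sweating
hyperhidrosis,adr,night sweats
agitation,adr,agitation
drowsiness,adr,drowsiness
drowsiness,adr,drowsy
appetite,adr,appetite
syncope,adr,fainting
syncope,adr,syncope
red eyes,adr,red eyes
red eyes,adr,bloodshot eyes
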