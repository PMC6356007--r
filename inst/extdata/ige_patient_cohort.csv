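subject_id,sex,age,epilepsy_duration,onset_age,absence,myoclonic,gtc
PAT01,M,49.6,30.6,19,0,0,1
PAT02,F,48.7,31.7,17,1,1,1
PAT03,M,47.4,31.4,16,0,0,1
PAT04,M,27.5,7.7,19.8,0,0,1
PAT05,F,32.1,12.1,20,1,0,1
PAT06,F,21.7,3.6,18.1,0,1,1
PAT07,F,38.8,26.8,12,1,0,1
PAT08,M,27.7,26.2,1.5,0,0,1
PAT09,M,35.6,26.6,9,0,1,1
PAT10,M,36.3,5.3,31,0,0,1
PAT11,F,24.6,9.6,15,1,1,1
PAT12,M,20.6,5.6,15,0,1,0
PAT13,F,37.9,23.9,14,0,1,0
PAT14,F,27.6,17.8,9.8,1,1,1
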