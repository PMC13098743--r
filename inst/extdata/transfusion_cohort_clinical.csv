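# Demographic and clinical table of the 15-subject ICU red-blood-cell
# transfusion pilot cohort analyzed by this package (one row per recruited
# subject). Subject 3 was discarded for poor optical SNR at both probe
# locations (included = FALSE); subject 2 has no blood-gas data. Hgb in
# g/dL, HCT in percent, RBC unit storage age in days.
id,sex,age,polytrauma,tbi,gcs,etiology,hgb_pre,hgb_post,hct_pre,hct_post,rbc_storage_days,included
1,F,21,yes,yes,4,traffic accident (motorcycle),8.5,9.6,26,29,30,TRUE
2,M,18,yes,yes,5,traffic accident (car),NA,NA,NA,NA,16,TRUE
3,M,55,no,no,15,suicide attempt (severe burns),7.6,8.9,23,27,21,FALSE
4,M,44,yes,yes,14,traffic accident (motorcycle),8.2,8.9,25,27,16,TRUE
5,M,16,yes,yes,7,traffic accident (motorcycle),8,9.2,24,28,17,TRUE
6,M,24,yes,yes,15,traffic accident (motorcycle),8.2,8.9,25,27,26,TRUE
7,M,70,no,no,15,stroke,9.2,9.8,28,29,29,TRUE
8,F,72,yes,yes,15,fall from height >3 m,7.6,8.7,23,26,25,TRUE
9,M,22,yes,yes,11,fall from height >3 m,8.9,10.5,27,32,21,TRUE
10,M,50,yes,yes,14,traffic accident (motorcycle),7.8,8.9,23,27,25,TRUE
11,F,65,no,no,15,stroke,7.9,9,24,27,21,TRUE
12,M,51,no,no,15,cerebral hematoma,7.8,8.8,23,26,21,TRUE
13,M,27,yes,yes,6,hit by a train,7.9,8.7,24,26,20,TRUE
14,M,44,yes,no,15,traffic accident (motorcycle),7.6,8.4,23,25,17,TRUE
15,M,26,no,no,15,severe burns,8,9.1,24,27,12,TRUE
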