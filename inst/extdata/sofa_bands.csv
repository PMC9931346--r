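component,measure,low,high,score
respiration,pao2_fio2,400,Inf,0
respiration,pao2_fio2,300,400,1
respiration,pao2_fio2,200,300,2
respiration,pao2_fio2,100,200,3
respiration,pao2_fio2,-Inf,100,4
coagulation,platelets,150,Inf,0
coagulation,platelets,100,150,1
coagulation,platelets,50,100,2
coagulation,platelets,20,50,3
coagulation,platelets,-Inf,20,4
liver,bilirubin,-Inf,1.2,0
liver,bilirubin,1.2,2,1
liver,bilirubin,2,6,2
liver,bilirubin,6,12,3
liver,bilirubin,12,Inf,4
cardiovascular,map,70,Inf,0
cardiovascular,map,-Inf,70,1
cardiovascular,vasopressor,1e-9,0.1,3
cardiovascular,vasopressor,0.1,Inf,4
cns,gcs,15,Inf,0
cns,gcs,13,15,1
cns,gcs,10,13,2
cns,gcs,6,10,3
cns,gcs,-Inf,6,4
renal,creatinine,-Inf,1.2,0
renal,creatinine,1.2,2,1
renal,creatinine,2,3.5,2
renal,creatinine,3.5,5,3
renal,creatinine,5,Inf,4
renal,urine_24h,500,Inf,0
renal,urine_24h,200,500,3
renal,urine_24h,-Inf,200,4
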