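fn,biomarker,weight
nervous_system,GCS,2
inflammation_infection,WBC,3
inflammation_infection,HR,2
inflammation_infection,Platelets,3
liver_function,SGOT,3
liver_function,SGPT,3
liver_function,Arterial_Lactate,3
liver_function,Total_Bilirubin,1
kidney_function,BUN,1
kidney_function,Creatinine,1
kidney_function,Glucose,1
coagulation,aPTT,1
coagulation,PT,3
coagulation,INR,2
respiratory,PaO2,3
respiratory,FiO2,2
respiratory,PaO2_FiO2,3
respiratory,Mechvent,2
cardiovascular,DiaBP,1
cardiovascular,Arterial_Lactate,3
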