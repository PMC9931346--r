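criterion,measure,low,high
temperature,temp,36,38
heart_rate,hr,-Inf,90
respiratory,rr,-Inf,20
respiratory,paco2,32,Inf
wbc,wbc,4,12
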