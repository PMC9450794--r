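group,n,mean_s,sd_s,min_s,median_s,max_s
osahs,9993,0.8636,0.271,0.55,0.8,2.95
primary,7691,1.002,0.3562,0.55,0.9,2.55
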