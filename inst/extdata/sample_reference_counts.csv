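characteristic,level,n,pct_printed
sex,female,7660,61.10
sex,male,4877,38.90
ethnicity,han,11579,92.36
ethnicity,other,958,7.64
grade,grade10,4974,39.67
grade,grade11,5503,43.89
grade,grade12,2060,16.43
domicile,rural,2451,19.55
domicile,urban,10086,80.45
accommodation,boarding,2257,18.00
accommodation,day,10280,82.00
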