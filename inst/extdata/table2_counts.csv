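tile_id,algorithm_id,total_count,fp,fn,identified,fnr_pct,fpr_pct,acd_pct
training,CA#1,45,15,2,32,6.25,46.88,53.13
training,CA#2,41,12,3,32,9.38,37.50,46.88
training,CA#3,47,16,1,32,3.13,50.00,53.13
training,CA#4,28,1,5,32,15.63,3.13,18.75
training,CA#5,27,0,5,32,15.63,0.00,15.63
training,CA#6,28,0,4,32,12.50,0.00,12.50
training,CA#7,33,5,4,32,12.50,15.63,28.13
training,CA#8,33,5,4,32,12.50,15.63,28.13
training,CA#9,33,1,0,32,0.00,3.13,3.13
training,CA#10,32,0,0,32,0.00,0.00,0.00
training,CA#11,32,0,0,32,0.00,0.00,0.00
test,CA#1,193,6,3,190,1.58,3.16,4.74
test,CA#2,167,0,23,190,12.11,0.00,12.11
test,CA#3,190,3,3,190,1.58,1.58,3.16
test,CA#4,172,0,18,190,9.47,0.00,9.47
test,CA#5,176,0,14,190,7.37,0.00,7.37
test,CA#6,171,0,19,190,10.00,0.00,10.00
test,CA#7,176,0,14,190,7.37,0.00,7.37
test,CA#8,180,0,10,190,5.26,0.00,5.26
test,CA#9,175,0,15,190,7.89,0.00,7.89
test,CA#10,184,0,6,190,3.16,0.00,3.16
test,CA#11,180,0,10,190,5.26,0.00,5.26
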