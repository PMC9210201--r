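week_of,n,flagged_n,tp_pct,tn_pct,fp_pct,fn_pct,insufficient_pct
2020-02-07,56,29,29,23,23,2,9
2020-02-14,58,29,21,17,33,0,10
2020-02-21,59,36,31,19,36,0,10
2020-02-28,62,39,27,15,40,0,6
2020-03-06,64,39,30,9,39,0,8
2020-03-13,64,37,34,16,33,0,9
2020-03-20,64,36,34,19,31,2,9
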