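subject,mean_nn,sdnn,lfnu,hfnu,lf_hf
1,0.05,1.58,2.20,2.32,4.36
2,0.08,1.70,7.89,4.65,13.00
3,0.11,2.50,3.41,2.56,5.94
4,0.11,9.92,5.7,8.89,12.44
5,0.19,4.79,7.96,6.53,12.89
6,0.13,2.89,5.56,6.99,11.43
7,0.13,2.58,2.20,3.40,5.71
8,0.10,6.98,3.86,5.83,9.02
9,0.09,3.24,7.74,5.57,12.65
10,0.16,9.87,7.83,2.91,10.53
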