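subject,mean_nn,sdnn,lfnu,hfnu,lf_hf
1,0.03,5.63,3.35,2.81,6.03
2,0.02,10.89,11.11,6.19,16.18
3,0.02,20.10,14.62,16.43,26.60
4,0.08,19.22,9.61,17.89,21.83
5,0.01,40.25,35.88,50.01,46.42
6,0.10,14.86,6.37,7.60,12.54
7,0.02,9.62,3.38,6.73,9.44
8,0.01,10.53,4.70,7.38,11.24
9,0.01,8.35,7.12,8.00,13.94
10,0.02,20.74,7.83,2.91,10.53
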