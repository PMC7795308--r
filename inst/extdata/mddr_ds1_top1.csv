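class,SDBN,BIN,SQB,ASMTP,TAN
31420,74.21,74.08,73.73,73.84,69.69
71523,27.97,28.26,26.84,15.03,25.94
37110,26.03,26.05,24.73,20.82,9.63
31432,39.79,39.23,36.66,37.14,35.82
42731,23.06,21.68,21.17,19.53,17.77
06233,19.29,14.06,12.49,10.35,13.87
06245,6.27,6.31,6.03,5.5,6.51
07701,14.05,11.45,11.35,7.99,8.63
06235,12.87,10.84,10.15,9.94,9.71
78374,17.47,14.25,13.08,13.9,13.69
78331,9.93,6.03,5.92,6.89,7.17
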