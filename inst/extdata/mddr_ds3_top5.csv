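class,SDBN,BIN,SQB,TAN
09249,31.61,25.72,17.8,24.17
12455,16.29,14.65,11.42,10.29
12464,20.9,16.55,16.79,15.22
31281,36.13,28.29,29.05,29.62
43210,22.09,14.41,14.12,16.07
71522,14.68,8.44,13.82,12.37
75721,41.07,30.02,30.61,25.21
78331,17.13,12.03,11.97,15.01
78348,26.93,20.76,21.14,24.67
78351,17.87,12.94,13.3,11.71
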