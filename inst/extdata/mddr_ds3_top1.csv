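class,SDBN,BIN,SQB,TAN
09249,19.47,15.33,10.99,12.12
12455,13.29,9.37,7.03,6.57
12464,12.91,8.45,6.92,8.17
31281,23.62,18.29,18.67,16.95
43210,14.23,7.34,6.83,6.27
71522,11.92,4.08,6.57,3.75
75721,29.08,20.41,20.38,17.32
78331,11.93,7.51,6.16,6.31
78348,9.17,9.79,8.99,10.15
78351,18.13,13.68,12.5,9.84
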