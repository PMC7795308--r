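class,SDBN,BIN,SQB,ASMTP,TAN
31420,89.03,87.61,87.75,86,83.49
71523,65.17,52.72,60.16,51.33,48.92
37110,41.25,48.2,39.81,23.87,21.01
31432,79.87,77.57,82,76.63,74.29
42731,31.92,26.63,28.77,32.9,29.68
06233,29.31,23.49,20.96,26.2,27.68
06245,21.06,14.86,15.39,15.5,16.54
07701,28.43,27.79,26.9,23.9,24.09
06235,27.82,23.78,22.47,23.6,20.06
78374,19.09,20.2,20.95,22.26,20.51
78331,16.21,11.8,10.31,15,16.2
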