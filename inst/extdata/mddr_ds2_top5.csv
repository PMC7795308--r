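class,SDBN,BIN,SQB,ASMTP,TAN
07707,73.9,74.81,74.22,76.17,70.39
07708,98.22,99.61,100,99.99,56.58
31420,95.64,65.46,95.24,95.75,88.19
42710,90.12,92.55,93,96.73,88.09
64100,99.05,99.22,98.94,98.27,93.75
64200,93.76,99.2,98.93,96.16,77.68
64220,96.01,91.32,90.9,94.13,52.19
64500,91.51,94.96,92.72,90.6,44.8
64350,86.94,91.47,93.75,98.6,91.71
75755,91.6,98.35,98.75,97.27,94.82
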