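class,SDBN,BIN,SQB,ASMTP,TAN
07707,83.19,72.18,72.09,67.86,61.84
07708,94.82,96,95.68,97.87,47.03
31420,79.27,79.82,78.56,73.51,65.1
42710,74.81,76.27,76.82,81.17,81.27
64100,93.65,88.43,87.8,86.62,80.31
64200,71.16,70.18,70.18,69.11,53.84
64220,68.71,68.32,67.58,66.26,38.64
64500,75.62,81.2,79.2,46.24,30.56
64350,85.21,81.89,81.68,68.01,80.18
75755,96.52,98.06,98.02,93.48,87.56
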