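problem,holdout_mode,accuracy,sensitivity,specificity
EMCI vs. LMCI,subject,53.08,23.96,42.78
AD vs. CN,subject,48.53,23.20,33.00
CN vs. EMCI,subject,40.04,25.14,20.07
CN vs. LMCI,subject,56.97,27.17,40.54
EMCI vs. AD,subject,45.24,28.00,24.26
LMCI vs. AD,subject,44.12,2.62,52.56
MCI vs. EMCI,subject,46.22,27.51,23.76
EMCI vs. LMCI,slice,83.90,79.39,88.47
AD vs. CN,slice,73.18,48.21,98.16
CN vs. EMCI,slice,86.90,85.75,88.00
CN vs. LMCI,slice,84.12,75.18,93.07
EMCI vs. AD,slice,79.55,82.36,76.74
LMCI vs. AD,slice,84.58,95.69,73.48
MCI vs. EMCI,slice,89.86,86.43,93.33
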