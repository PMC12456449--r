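label,y1,n1,y2,n2
study_01,2,23,5,16
study_02,2,164,22,164
study_03,1,246,30,246
study_04,6,99,15,99
study_05,6,133,27,200
study_06,1,58,9,87
study_07,15,288,54,202
study_08,0,24,4,17
study_09,12,348,29,348
study_10,3,83,10,124
study_11,1,30,5,45
study_12,5,173,36,173
study_13,2,29,4,29
study_14,0,72,1,50
study_15,2,42,7,63
study_16,2,148,22,148
study_17,11,266,36,186
study_18,1,293,28,293
study_19,0,58,0,58
study_20,3,148,16,148
study_21,3,88,18,62
study_22,3,423,39,296
study_23,2,29,15,44
study_24,5,71,7,71
study_25,32,288,54,432
study_26,2,341,47,239
study_27,0,137,13,137
study_28,4,96,12,96
study_29,2,128,11,90
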