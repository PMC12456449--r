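label,n1,n2,mi1,mi2,cvd1,cvd2
trial_01,2635,2634,17,7,9,3
trial_02,1456,2895,14,15,8,0
trial_03,998,499,10,1,1,0
trial_04,54,27,0,0,0,0
trial_05,157,78,1,0,0,0
trial_06,270,135,2,1,0,0
trial_07,353,176,2,1,2,0
trial_08,271,271,1,0,2,0
trial_09,107,54,0,0,0,0
trial_10,326,326,2,0,1,1
trial_11,738,369,4,1,3,1
trial_12,267,267,4,1,1,0
trial_13,240,240,0,1,0,0
trial_14,350,350,1,4,2,1
trial_15,96,48,0,0,0,0
trial_16,218,218,0,2,1,0
trial_17,375,188,3,1,4,1
trial_18,1200,600,2,0,3,2
trial_19,89,44,0,1,0,0
trial_20,407,204,3,2,1,0
trial_21,40,40,0,0,0,0
trial_22,57,57,0,0,0,0
trial_23,118,59,0,1,0,0
trial_24,198,198,0,1,0,0
trial_25,187,187,2,1,0,0
trial_26,561,280,1,0,1,1
trial_27,478,478,5,1,1,0
trial_28,577,577,4,2,4,0
trial_29,640,640,2,0,0,0
trial_30,377,188,2,2,0,0
trial_31,168,168,1,1,0,0
trial_32,299,150,1,0,1,0
trial_33,871,436,5,3,2,0
trial_34,177,177,1,0,1,0
trial_35,742,371,5,2,1,0
trial_36,209,104,1,0,1,0
trial_37,1200,600,3,2,2,2
trial_38,115,115,1,0,0,0
trial_39,874,874,5,0,9,0
trial_40,251,251,1,1,0,0
trial_41,83,83,0,0,0,0
trial_42,40,20,0,0,0,0
trial_43,286,143,1,0,0,0
trial_44,177,88,1,0,0,0
trial_45,116,58,0,0,0,0
trial_46,148,148,1,0,0,0
trial_47,119,60,0,0,0,0
trial_48,93,93,0,0,0,0
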