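patient_id,hdl_c,ldl_c,total_chol,triglycerides,trig_to_hdl,statin_use
p001,53.93,95.03,189.57,209.99,3.89,FALSE
p002,36.62,56.69,197.55,296.09,8.09,TRUE
p003,44.09,98.53,208.12,81.8,1.86,TRUE
p004,46.53,134.58,155.51,120.64,2.59,FALSE
p005,44.45,152.28,191.16,126.94,2.86,FALSE
p006,40.14,91.81,120.06,166.16,4.14,TRUE
p007,55.47,96.31,149.9,120.4,2.17,TRUE
p008,40.23,57.16,147.77,52.49,1.3,TRUE
p009,61.39,114.96,97.75,56.61,0.92,TRUE
p010,40.49,86.36,176.16,211.11,5.21,TRUE
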