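patient_id,side,segment,fd,is_main,calcified_shadow
p001,right,common-carotid,1.1301,TRUE,FALSE
p001,right,internal-carotid,1.1692,FALSE,FALSE
p001,right,bulb,1.1402,FALSE,FALSE
p002,right,common-carotid,1.1158,TRUE,FALSE
p002,right,internal-carotid,1.0845,FALSE,FALSE
p002,left,internal-carotid,1.1131,FALSE,FALSE
p002,left,common-carotid,1.1345,FALSE,FALSE
p002,left,bulb,1.0872,FALSE,FALSE
p002,left,bulb,1.0995,FALSE,FALSE
p003,right,bulb,1.182,TRUE,FALSE
p003,left,bulb,1.1564,FALSE,FALSE
p003,right,bulb,1.1544,FALSE,FALSE
p003,left,internal-carotid,1.1677,FALSE,FALSE
p003,right,bulb,1.1552,FALSE,FALSE
p003,right,internal-carotid,1.1753,FALSE,FALSE
p004,left,bulb,1.1107,TRUE,FALSE
p004,left,common-carotid,1.0774,FALSE,FALSE
p004,right,internal-carotid,1.0849,FALSE,FALSE
p004,right,common-carotid,1.0768,FALSE,FALSE
p004,right,bulb,1.0669,FALSE,FALSE
p005,left,bulb,1.1531,TRUE,FALSE
p005,right,common-carotid,1.152,FALSE,FALSE
p005,left,bulb,1.1338,FALSE,FALSE
p006,left,bulb,1.1492,TRUE,FALSE
p006,left,bulb,1.1527,FALSE,FALSE
p006,right,common-carotid,1.1484,FALSE,FALSE
p007,left,common-carotid,1.0844,TRUE,FALSE
p007,left,internal-carotid,1.0638,FALSE,FALSE
p007,right,internal-carotid,1.0544,FALSE,FALSE
p007,right,bulb,1.0212,FALSE,FALSE
p008,left,common-carotid,1.1938,TRUE,FALSE
p008,left,common-carotid,1.1975,FALSE,FALSE
p008,right,common-carotid,1.1639,FALSE,FALSE
p008,right,common-carotid,1.1937,FALSE,FALSE
p008,left,common-carotid,1.181,FALSE,FALSE
p009,left,common-carotid,1.1275,TRUE,FALSE
p009,right,common-carotid,1.1756,FALSE,FALSE
p009,left,common-carotid,1.0944,FALSE,FALSE
p010,right,internal-carotid,1.1402,TRUE,FALSE
p010,left,bulb,1.1762,FALSE,FALSE
p010,left,common-carotid,1.1261,FALSE,FALSE
p010,left,internal-carotid,1.1386,FALSE,FALSE
p010,left,internal-carotid,1.1376,FALSE,FALSE
p010,left,common-carotid,1.1136,FALSE,FALSE
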