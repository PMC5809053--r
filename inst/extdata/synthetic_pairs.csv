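subject_id,m1,m2
s001,1.185,1.1925
s002,1.0881,1.1087
s003,1.1477,1.1612
s004,1.1783,1.1501
s005,1.1792,1.1319
s006,1.1256,1.1381
s007,1.1912,1.1832
s008,1.1067,1.1532
s009,1.2214,1.2085
s010,1.1243,1.1431
s011,1.1935,1.1916
s012,1.2354,1.2138
s013,1.0968,1.1047
s014,1.1163,1.1344
s015,1.1381,1.1321
s016,1.1359,1.1648
s017,1.1135,1.1348
s018,1.0201,1.0337
s019,1.0058,0.9974
s020,1.188,1.1916
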