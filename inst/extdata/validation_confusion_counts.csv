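exam_id,sjt_snorer,n_snores,tp,fp,tn,fn
EX01,No,22,21,76,112,1
EX02,No,866,865,25,965,1
EX03,Yes,656,656,15,759,0
EX04,Yes,2797,2789,52,3081,8
EX05,Yes,293,286,22,345,7
EX06,Yes,1893,1885,211,2252,8
EX07,No,90,90,25,149,0
EX08,Yes,234,210,20,314,24
EX09,Yes,826,819,54,934,7
EX10,No,32,29,164,242,3
EX11,Yes,932,924,28,1074,8
EX12,Yes,880,860,22,998,20
EX13,Yes,293,286,22,345,7
EX14,Yes,1140,1124,46,1308,16
EX15,Yes,1649,1639,14,1775,10
EX16,Yes,2136,2127,67,2441,9
EX17,Yes,1240,1237,17,1301,3
EX18,No,21,21,24,55,0
EX19,Yes,4213,4209,28,4483,4
EX20,Yes,1467,1457,16,1597,10
EX21,Yes,4129,4065,28,4493,64
EX22,Yes,2617,2601,14,2905,16
EX23,Yes,354,353,17,437,1
EX24,Yes,729,723,25,800,6
EX25,Yes,4619,4589,61,4908,30
EX26,Yes,1624,1622,28,1789,2
EX27,Yes,1090,1075,19,1239,15
EX28,Yes,3911,3903,11,4144,8
EX29,Yes,1530,1525,68,1676,5
EX30,Yes,1315,1300,12,1497,15
EX31,Yes,378,360,100,560,18
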