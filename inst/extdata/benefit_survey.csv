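sample,profile,category,count
1,111,1,60
1,112,2,48
1,121,3,116
1,122,4,269
1,211,5,41
1,212,6,144
1,221,7,174
1,222,8,908
2,111,1,1
2,112,2,1
2,121,3,13
2,122,4,24
2,211,5,2
2,212,6,2
2,221,7,4
2,222,8,420
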