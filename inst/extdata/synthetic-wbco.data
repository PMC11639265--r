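1000001,5,1,1,1,2,1,3,1,1,2
1000002,5,4,4,5,7,10,3,2,1,4
1000003,3,1,1,1,2,2,3,1,1,2
1000004,6,8,8,1,3,4,3,7,1,4
1000005,4,1,1,3,2,1,3,1,1,2
1000006,8,10,10,8,7,10,9,7,1,4
1000007,1,1,1,1,2,10,3,1,1,2
1000008,2,1,2,1,2,?,3,1,1,2
1000009,2,1,1,1,2,1,1,1,5,2
1000010,4,2,1,1,2,1,2,1,1,2
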