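63 1 1 145 233 1 2 150 0 2.3 3 0 6 1
67 1 4 160 286 0 2 108 1 1.5 2 3 3 2
67 1 4 120 229 0 2 129 1 2.6 2 2 7 2
37 1 3 130 250 0 0 187 0 3.5 3 0 3 1
41 0 2 130 204 0 2 172 0 1.4 1 0 3 1
56 1 2 120 236 0 0 178 0 0.8 1 0 3 1
62 0 4 140 268 0 2 160 0 3.6 3 2 3 2
57 0 4 120 354 0 0 163 1 0.6 1 0 3 1
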