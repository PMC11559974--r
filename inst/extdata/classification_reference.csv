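community,mixing,coherence,fortress,classification
1,0.54,1.00,0.17,sink
2,0.46,0.93,0.98,source
3,0.48,0.95,1.00,source
4,0.39,0.88,1.00,source
5,0.18,1.00,1.00,impermeable
6,0.45,0.98,0.81,sink
7,0.52,1.00,0.97,impermeable
8,0.50,0.82,0.99,source
9,0.29,1.00,0.06,sink
10,0.42,0.91,0.90,permeable
11,0.26,1.00,1.00,impermeable
12,0.40,1.00,1.00,impermeable
13,0.25,0.97,0.95,impermeable
14,0.42,0.98,0.98,impermeable
15,0.14,0.97,1.00,impermeable
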