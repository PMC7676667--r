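"age","qx"
60,0.007
61,0.007698
62,0.008465
63,0.009308
64,0.010236
65,0.011256
66,0.012378
67,0.013611
68,0.014968
69,0.01646
70,0.0181
71,0.019904
72,0.021887
73,0.024069
74,0.026467
75,0.029105
76,0.032006
77,0.035195
78,0.038703
79,0.04256
80,0.046801
81,0.051465
82,0.056594
83,0.062235
84,0.068437
85,0.075257
86,0.082757
87,0.091005
88,0.100074
89,0.110047
90,0.121014
91,0.133075
92,0.146337
93,0.16092
94,0.176958
95,0.194593
96,0.213986
97,0.235311
98,0.258762
99,0.28455
100,0.312908
101,0.344092
102,0.378384
103,0.416094
104,0.457561
105,0.503161
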