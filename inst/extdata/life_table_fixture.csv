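"age","q"
57,0.005
58,0.00552044756836906
59,0.00609506827102238
60,0.00672950096316178
61,0.00742997144568474
62,0.00820335356007638
63,0.00905723664263906
64,0.01
65,0.0110408951367381
66,0.0121901365420448
67,0.0134590019263236
68,0.0148599428913695
69,0.0164067071201528
70,0.0181144732852781
71,0.02
72,0.0220817902734762
73,0.0243802730840895
74,0.0269180038526471
75,0.029719885782739
76,0.0328134142403055
77,0.0362289465705563
78,0.04
79,0.0441635805469525
80,0.048760546168179
81,0.0538360077052942
82,0.0594397715654779
83,0.0656268284806111
84,0.0724578931411125
85,0.08
86,0.0883271610939051
87,0.0975210923363581
88,0.107672015410588
89,0.118879543130956
90,0.131253656961222
91,0.144915786282225
92,0.16
93,0.17665432218781
94,0.195042184672716
95,0.215344030821177
96,0.237759086261912
97,0.262507313922444
98,0.28983157256445
99,0.32
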