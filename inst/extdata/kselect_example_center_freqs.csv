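k,f1,f2,f3,f4,f5,f6,f7,f8,f9,f10
2,0.0062,0.0356,,,,,,,,
3,0.0061,0.0355,0.3122,,,,,,,
4,0.0061,0.0355,0.2406,0.3831,,,,,,
5,0.0061,0.0353,0.1729,0.3072,0.4327,,,,,
6,0.0055,0.0296,0.0419,0.1847,0.3103,0.4337,,,,
7,0.0054,0.0293,0.0413,0.1473,0.2506,0.3480,0.4448,,,
8,0.0054,0.0292,0.0410,0.1375,0.2293,0.3061,0.3796,0.4615,,
9,0.0054,0.0288,0.0404,0.1097,0.1796,0.2483,0.3165,0.3894,0.4665,
10,0.0053,0.0288,0.0403,0.1067,0.1737,0.2390,0.3030,0.3617,0.4231,0.4779
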