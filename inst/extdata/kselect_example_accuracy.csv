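k,a1,a2,a3,a4,a5,a6,a7,a8,a9
2,1.0037,1.0014,,,,,,,
3,1.0046,1.0019,1.2976,,,,,,
4,1.0088,1.0042,1.3910,1.2469,,,,,
5,1.1065,1.1915,4.1299,1.6630,1.3943,,,,
6,1.0092,1.0113,1.0152,1.2540,1.2381,1.2464,,,
7,1.0036,1.0043,1.0055,1.0710,1.0932,1.1369,1.1717,,
8,1.0096,1.0122,1.0157,1.2540,1.2764,1.2324,1.1993,1.1852,
9,1.0014,1.0017,1.0022,1.0284,1.0341,1.0389,1.0445,1.0766,1.1026
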