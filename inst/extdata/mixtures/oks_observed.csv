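items,raw_percent
unit,73.1
7,15.6
4,3.3
6,2.7
9,2.1
10,1.5
1,0.9
12,0.9
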