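items,raw_percent
unit,87.9
5,5.1
1,2.6
4,1.8
3,1.5
2,1.1
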