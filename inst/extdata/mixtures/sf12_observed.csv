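items,raw_percent,label
unit,56.1,unit non-response
3,20.3,only item 2b
7,6.5,only item 4b
3;5,4.5,items 2b and 3b
5,4.0,only item 3b
3;5;7,3.5,"items 2b, 3b and 4b"
3;7,3.3,items 2b and 4b
11,1.8,only item 6c
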