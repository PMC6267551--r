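person_id,c1,c2,c3,c4
1,7,5,4,1
2,7,2,5,1
3,3,4,6,1
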