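lower,upper,level,degree,class
1.0,1.5,Oligosaprobic,Non-polluted,I
1.5,1.8,Oligosaprobic to b-Mesosaprobic,Waters without organic load,I-II
1.8,2.3,b-Mesosaprobic,Waters with a moderate organic load,II
2.3,2.7,b-Mesosaprobic to a-Mesosaprobic,Waters with critical organic load,II-III
2.7,3.2,a-Mesosaprobic,Waters strongly polluted,III
3.2,3.5,a-Mesosaprobic to polysaprobic,Waters are very strongly polluted,III-IV
3.5,4.0,Polysaprobic,Waters exceptionally polluted,IV
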