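(((((ranid2:60,ranid3:60):20,ranid4:80):40,(dicro1:70,dicro2:70):50):80,(ranid1:150,megop1:150):50):150,((sala1:90,(sala2:80,sala3:80):10):120,sala4:210):140,((caec1:100,caec2:100):80,caec3:180):170)root;
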