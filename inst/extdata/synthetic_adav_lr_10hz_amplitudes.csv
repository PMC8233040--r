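pulse_index,normalized_amplitude,isi_ms
1,1,100
2,0.8543,100
3,0.7452,100
4,0.6905,100
5,0.6639,100
6,0.6509,100
7,0.6447,100
8,0.6416,100
9,0.6402,100
10,0.6394,100
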