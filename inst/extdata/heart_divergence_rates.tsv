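region	Dh_per_kb	Dnh_per_kb
proximal	5.66	60.01
tele	5.47	59.53
controls	6.42	62.34
neutral	9.14	74.9
hacns	17.24	29.75
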