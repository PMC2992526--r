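P01
P02
P03
P04
P05
P06
P07
P08
P09
P10
P11
P12
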