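>GTTAATCATTAA synTF1 8.0
0.05 0.05 0.85 0.05
0.05 0.05 0.05 0.85
0.05 0.05 0.05 0.85
0.80 0.05 0.10 0.05
0.80 0.10 0.05 0.05
0.05 0.10 0.05 0.80
0.10 0.70 0.10 0.10
0.80 0.05 0.10 0.05
0.05 0.05 0.05 0.85
0.05 0.05 0.05 0.85
0.80 0.05 0.10 0.05
0.80 0.10 0.05 0.05
>TGTTTAC synTF2 6.0
0.05 0.10 0.05 0.80
0.05 0.05 0.85 0.05
0.05 0.05 0.05 0.85
0.05 0.05 0.05 0.85
0.05 0.05 0.05 0.85
0.80 0.05 0.10 0.05
0.10 0.70 0.10 0.10
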