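true,C&J,AS,BJ,BP,TRANS
C&J,228,0,0,0,22
AS,0,107,0,0,25
BJ,0,0,92,0,13
BP,0,1,0,138,4
TRANS,2,7,5,5,3215
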