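true,C&J,AS,BJ,BP,TRANS
C&J,434,4,0,0,90
AS,3,214,0,2,51
BJ,0,0,174,0,29
BP,2,0,0,280,43
TRANS,47,12,12,20,3961
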