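class,ACC_stage1,ACC_stage2,PPV_stage1,PPV_stage2,TPR_stage1,TPR_stage2
C&J,99.4,97.3,99.1,89.3,91.2,82.2
AS,99.1,98.7,93.0,93.0,81.1,79.3
BJ,99.5,99.2,94.8,93.5,87.6,85.7
BP,99.7,98.8,96.5,92.7,96.5,86.2
TRANS,97.9,94.3,98.0,94.9,99.4,97.8
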