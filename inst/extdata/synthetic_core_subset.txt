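sM_01
sM_02
sM_03
sM_04
sM_05
sM_06
sM_07
sM_08
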