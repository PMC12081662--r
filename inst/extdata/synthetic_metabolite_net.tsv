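# synthetic stand-in for a small metabolite-style network (generated, not biological data)
sM_01	sM_03
sM_02	sM_03
sM_01	sM_04
sM_03	sM_04
sM_04	sM_05
sM_03	sM_05
sM_04	sM_06
sM_03	sM_06
sM_01	sM_07
sM_03	sM_07
sM_03	sM_08
sM_01	sM_08
sM_03	sM_09
sM_07	sM_09
sM_08	sM_10
sM_07	sM_10
sM_03	sM_11
sM_05	sM_11
sM_05	sM_12
sM_08	sM_12
sM_10	sM_13
sM_01	sM_13
sM_03	sM_14
sM_01	sM_14
sM_07	sM_15
sM_04	sM_15
sM_05	sM_16
sM_07	sM_16
sM_11	sM_17
sM_05	sM_17
sM_02	sM_18
sM_13	sM_18
sM_04	sM_19
sM_07	sM_19
sM_03	sM_20
sM_08	sM_20
sM_15	sM_21
sM_05	sM_21
sM_11	sM_22
sM_15	sM_22
sM_07	sM_23
sM_03	sM_23
sM_21	sM_24
sM_01	sM_24
sM_21	sM_25
sM_11	sM_25
sM_01	sM_26
sM_08	sM_26
sM_15	sM_27
sM_07	sM_27
sM_17	sM_28
sM_06	sM_28
sM_20	sM_29
sM_01	sM_29
sM_23	sM_30
sM_18	sM_30
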