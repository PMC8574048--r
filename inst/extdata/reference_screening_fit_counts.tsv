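risk_group	fit_negative	fit_positive
screening_control	226	444
LRL	78	208
IRL	43	309
HRL	14	212
screening_CRC	1	69
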