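risk_group	n	mean_adjusted_prs	sd_adjusted_prs
population_control	1008	131.7	7.2
screening_control	670	131.5	7.1
LRL	286	131.8	7.4
IRL	352	132.6	7.0
HRL	226	133.7	7.4
screening_CRC	70	133.9	6.4
clinical_CRC	1007	134.5	7.0
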