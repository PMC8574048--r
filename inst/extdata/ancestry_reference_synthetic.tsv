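label	PC1	PC2	PC3	PC4	PC5
EUR	-8.0	-2.0	0.1	0.0	0.0
EUR	-7.6	-1.8	-0.1	0.1	0.0
EUR	-8.4	-2.2	0.0	-0.1	0.0
AFR	12.0	-3.0	0.2	0.0	0.1
AFR	11.5	-3.3	-0.2	0.1	-0.1
AFR	12.5	-2.7	0.0	-0.1	0.0
LAT	-1.0	6.0	-0.1	0.0	0.0
LAT	-0.6	5.7	0.1	-0.1	0.1
LAT	-1.4	6.3	0.0	0.1	-0.1
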