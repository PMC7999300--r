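sample_id	SNS_TRUNK_1	SNS_TRUNK_2	SNS_TRUNK_3	SNS_TRUNK_4	CNA_TRUNK	SNS_B1_1	SNS_B1_2	SNS_B1_3	SNS_B1_4	SNS_B1_5	CNA_B2_1	CNA_B2_2	CNA_B2_3	SNS_B3_1	SNS_B3_2	SNS_B3_3	SNS_B3_4	SNS_B3_5	SNS_B3_6	SNS_B3A_1	SNS_B3A_2	SNS_B3A_3	SNS_B3A_4	CNA_B3A_1	CNA_B3A_2	CNA_B3A_3	SNS_B3Aa_1	SNS_B3Aa_2	SNS_B3Aa_3	SNS_B3Aa_4	SNS_B3Aa_5	SNS_B3Aa_6	CNA_B3Aa	SNS_B3B	CNA_B3B_1	CNA_B3B_2	SNS_B3Ba_1	SNS_B3Ba_2	SNS_B3Ba_3	SNS_B3Ba_4	SNS_B3Ba_5	SNS_B3Ba_6	SNS_B3Ba_7	CNA_B3Ba	SNS_B3Bb	SNS_B3Bb1	SNS_B3Bb1a	SNS_B3Bb1b	SNS_X1	SNS_X2
O1A	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3
O1B	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	3	3	3	3	3	3	3	3	0	0	0	0	3	3
O1C	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	3	0	0	0	3	3
O2A	3	3	3	3	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
O2B	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	3	3	3	0	0	0
O2C	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	3	3	0	3	0	0
O2D	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	3	0	0	0	0	0
MT1	3	3	3	3	3	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
MT2	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	3	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
MT3	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	3	0	0	0	0	0
MT4	3	3	3	3	3	0	0	0	0	0	0	0	0	3	3	3	3	3	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	3	3	0	0	0	0	0	0	0	0	3	0	0	0	0	0
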