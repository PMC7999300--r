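sample_id	SNS01	SNS02	SNS03	SNS04	SNS05	SNS06	SNS07	SNS08	SNS09	SNS10	SNS11	SNS12	SNS13	SNS14	SNS15	SNS16	SNS17	SNS18	SNS19	SNS20	SNS21	SNS22
O1	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	3	0	0	0	0	0	0
O2	3	3	3	3	3	3	3	3	3	3	3	3	3	3	0	0	3	3	3	3	3	3
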