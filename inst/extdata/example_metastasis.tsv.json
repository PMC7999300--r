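{"roles":{"O1A":"organoid","O1B":"organoid","O1C":"organoid","O2A":"organoid","O2B":"organoid","O2C":"organoid","O2D":"organoid","MT1":"metastasis","MT2":"metastasis","MT3":"metastasis","MT4":"metastasis"},"thresholds":[]}
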