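{"roles":{"O1":"organoid","O2":"organoid"},"thresholds":[]}
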