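{"rate":50,"range_g":2,"subject_id":"S01","position":"pocket","annotations":[]}
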