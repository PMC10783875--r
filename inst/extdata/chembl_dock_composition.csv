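measure_type,pairs,assays
IC50,231948,14954
Ki,69127,5397
Kd,12149,1335
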