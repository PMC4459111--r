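key,value
total_claims,513886
total_patients,269843
single_claim_patients,180597
multi_claim_patients,89246
multi_claim_claims,333289
episodes_from_multi_claim_patients,114404
total_episodes,295001
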