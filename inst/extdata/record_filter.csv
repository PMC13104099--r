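reason,n_removed
duplicate_rct,13
protocol_only_no_results,17
non_english_language,1
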