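term	category
missense_variant	nonsynonymous
stop_gained	nonsynonymous
stop_lost	nonsynonymous
start_lost	nonsynonymous
protein_altering_variant	nonsynonymous
nonsynonymous	nonsynonymous
non_synonymous_coding	nonsynonymous
synonymous_variant	synonymous
stop_retained_variant	synonymous
start_retained_variant	synonymous
synonymous	synonymous
synonymous_coding	synonymous
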