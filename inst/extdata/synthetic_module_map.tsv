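module	term_id
cytochemokine_response	T:cytochemokine_response_01
cytochemokine_response	T:cytochemokine_response_02
cytochemokine_response	T:cytochemokine_response_03
gliogenesis	T:gliogenesis_01
gliogenesis	T:gliogenesis_02
gliogenesis	T:gliogenesis_03
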