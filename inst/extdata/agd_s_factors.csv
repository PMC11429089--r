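# s-factors for the X-ray spectrum (target/filter combination), per the
# EUREF average-glandular-dose formalism. Version 1.
target_filter,s
Mo/Mo,1.000
Mo/Rh,1.017
Rh/Rh,1.061
Rh/Al,1.044
W/Rh,1.042
W/Ag,1.042
W/Al,1.050
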