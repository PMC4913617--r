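machine,fee_2011,fee_2014
tractor_small,25.01,23.90
tractor_medium,35.81,35.28
tractor_large,50.21,44.61
combine,121.00,123.48
swather,57.00,57.87
baler,45.63,53.51
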