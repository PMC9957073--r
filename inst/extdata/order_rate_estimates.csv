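order,fusion_2p,fission_2p,fusion_3p,fission_3p,polyploidy_3p
Blattodea,0.201,0.223,0.119,0.082,0.001
Coleoptera,0.036,0.064,0.016,0.025,0.001
Diptera,0.863,0.678,0.692,0.521,0.008
Hemiptera,0.106,0.121,0.984,0.927,0.003
Hymenoptera,0.555,0.583,0.042,0.064,0.009
Lepidoptera,13.005,12.842,0.508,0.548,0.008
Odonata,0.004,0.001,0.004,0.001,0.035
Orthoptera,0.161,0.216,0.039,0.025,0.121
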