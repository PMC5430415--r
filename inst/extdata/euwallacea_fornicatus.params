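# Fitted parameter set for Euwallacea fornicatus (polyphagous shot-hole borer)
# Flat key-value format: one Table-style mnemonic per line.
DV0 = 15
DV1 = 26
DV2 = 35
DV3 = 40
SM0 = 0.05
SM1 = 0.3
SM2 = 1
SM3 = 2.5
TTCS = -10
THCS = -0.005
TTHS = 42
THHS = 0.0002
SMDS = 0.05
HDS = -0.001
SMWS = 2.5
HWS = 0.005
PDD = 373
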