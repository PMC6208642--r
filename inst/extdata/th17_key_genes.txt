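# Key genes of the Th17 cell differentiation pathway (13 genes):
# IL-6/TGF-beta signalling through STAT3/RORC to the IL-17 effector arm.
IL6
TGFB1
STAT3
RORC
RORA
IL17A
IL17F
IL21
IL21R
IL22
IL23A
IL23R
IL1B
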