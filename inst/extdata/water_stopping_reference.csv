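# Reference proton mass stopping powers in liquid water (MeV cm^2/g),
# transcribed from the standard tabulation; used as an independent
# cross-check grid for the package's Bethe-based tables (5% tolerance).
energy_mev,stopping_mev_cm2_g
0.5,428.0
1.0,260.8
2.0,159.1
5.0,79.11
10.0,45.67
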