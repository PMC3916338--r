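# Default DRN-LHA circuit parameters
# J in pA/Hz, tau in s, g in Hz/pA, currents in pA
g.5HT = 0.033
g.GABA_DRN = 0.061
g.Ox = 0.205
g.GABA_LHA = 0.195
I0.5HT = 0.13
I0.GABA_DRN = 0
I0.Ox = 0
I0.GABA_LHA = 0
Ibg.5HT = 231.47
Ibg.GABA_DRN = 246
Ibg.Ox = 617.6
Ibg.GABA_LHA = 20.9
J.5HT_auto = 16
J.Ox_to_5HT = 15
J.5HT_to_GABA_DRN = 10
J.Ox_to_GABA_DRN = 5
J.Ox_auto = 6
J.5HT_to_Ox = 6
J.Ox_to_GABA_LHA = 0
J.5HT_to_GABA_LHA = 6
J.GABA_DRN_to_5HT = 5
J.GABA_DRN_self = 5
J.GABA_LHA_to_Ox = 118
J.GABA_LHA_self = 5
tau.5HT_auto = 1
tau.Ox_to_5HT = 60
tau.5HT_to_GABA_DRN = 60
tau.Ox_to_GABA_DRN = 5
tau.Ox_auto = 10
tau.5HT_to_Ox = 2
tau.Ox_to_GABA_LHA = 10
tau.5HT_to_GABA_LHA = 2
sign.5HT_to_GABA_LHA = 1
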