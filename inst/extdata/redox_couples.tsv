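# Standard (pH 7) redox potentials of the half-reaction couples used in the
# nitrate-dependent AOM reconstruction. E0' in mV; n_electrons per turnover.
name	e0_prime_mv	n_electrons
NO3-/NO2-	433	2
CO2/CH4	-244	8
CoM-S-S-CoB/CoM-SH+CoB-SH	-143	2
menaquinone	-80	2
methanophenazine	-165	2
F420	-360	2
ferredoxin	-500	2
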