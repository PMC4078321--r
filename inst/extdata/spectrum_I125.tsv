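# nuclide: I-125
# half_life_s: 5132160
# daughter_Z: 52
# local_energy_sub1kev_keV: 2.11
# n_sub1kev_ae: 21.2
# Curated non-radiative emission groups for I-125 (EC decay, Te-125 daughter).
# CE lines: the four conversion lines of the 35.5 keV transition; AE: K-Auger
# groups and the mean L-Auger group from the ~1.6 K-vacancies per decay
# (EC capture + K conversion) at Te fluorescence yields; sub-1-keV M/N Auger
# energy is carried by the local-deposit term.
kind	energy_keV	yield	shape
CE	3.678	0.793	-
CE	30.553	0.1062	-
CE	34.482	0.02146	-
CE	35.276	0.00437	-
AE	22.70	0.151	-
AE	26.50	0.044	-
AE	30.20	0.004	-
AE	3.19	1.62	-
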