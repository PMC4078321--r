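# nuclide: I-123
# half_life_s: 47592
# daughter_Z: 52
# local_energy_sub1kev_keV: 1.25
# n_sub1kev_ae: 12.94
# Curated non-radiative emission groups for I-123 (EC decay, Te-123 daughter).
# CE lines: dominant conversion lines of the 159 keV transition plus weak
# high-energy lines; AE: K-Auger groups (KLL/KLX/KXY) and the mean L-Auger
# group; M/N Auger energy (< 1 keV) is carried by the local-deposit term.
kind	energy_keV	yield	shape
CE	127.17	0.1360	-
CE	154.62	0.0177	-
CE	158.10	0.00386	-
CE	158.97	0.00079	-
CE	408.40	0.00021	-
CE	497.10	0.00028	-
AE	22.70	0.0873	-
AE	26.50	0.0254	-
AE	30.20	0.0023	-
AE	3.19	0.95	-
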