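# nuclide: I-131
# half_life_s: 693360
# daughter_Z: 54
# local_energy_sub1kev_keV: 0.0783
# n_sub1kev_ae: 0.644
# Curated non-radiative emission groups for I-131 (beta-minus decay, Xe-131
# daughter). Beta: the six independent transition spectra (endpoints/yields),
# first-forbidden branches approximated with the allowed shape. CE: conversion
# lines of the 80.2, 284.3 and 364.5 keV transitions. The delayed Xe-131m
# (163.9 keV IT) contribution is excluded. Sub-1-keV AE energy is carried by
# the local-deposit term.
kind	energy_keV	yield	shape
CE	45.62	0.0354	-
CE	74.97	0.0060	-
CE	79.30	0.0012	-
CE	249.74	0.0025	-
CE	329.93	0.0155	-
CE	359.70	0.00246	-
CE	363.62	0.00050	-
AE	24.60	0.0059	-
AE	3.43	0.0500	-
BETA	247.9	0.0208	allowed
BETA	303.9	0.0062	first_forbidden
BETA	333.8	0.0727	allowed
BETA	606.3	0.8960	allowed
BETA	629.7	0.0005	allowed
BETA	806.9	0.0037	first_forbidden
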