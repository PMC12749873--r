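# Bound neutron scattering and absorption constants per isotopic species.
# Columns:
#   species            label used throughout the package
#   mass_amu           atomic mass (natural-abundance average for H, B, O, Al)
#   sigma_scatt_barn   total bound scattering cross-section 4*pi*b^2 (coh + inc)
#   sigma_abs_barn     absorption cross-section at E_ref = 25.3 meV
# Values from the standard compilation of bound scattering lengths and
# cross-sections (Sears, Neutron News 3(3), 1992). All overridable at run time.
species,mass_amu,sigma_scatt_barn,sigma_abs_barn
H,1.00794,82.02,0.3326
B,10.811,5.24,767.0
B10,10.0129,3.1,3835.0
B11,11.0093,5.77,0.0055
O,15.999,4.232,0.00019
Al,26.98154,1.503,0.231
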