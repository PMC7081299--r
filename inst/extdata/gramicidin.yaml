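# Gramicidin A1 configuration: first Talbot order, argon seeding.
# Units are encoded in the key names; conversion to SI happens on load.
mass_amu: 1882
wavelength_nm: 157.63
sigma_m2: 4.7e-20        # VUV depletion cross section
alpha_v_m3: 1.57e-28     # ensemble-mean polarizability volume
n0_eff: 3                # effective antinode photon number (working point)
reflectivity: 0.97
coherence_factor: 0.76
velocity_m_s: 600
divergence_mrad: 0.4
tilt_mrad: 1.7
order_n: 1
tau_off_ns: 200
gravity_m_s2: 9.81
extra_acceleration_m_s2: 0
grating_shift_nm: 0
mirror_offset_nm: 0
grating_form: realistic
seed: 20200319
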