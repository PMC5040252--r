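# Transwell migration model parameter preset.
# Units: D_u, D_phi cm^2/h; chi1 cm^3/(ul h); chi2, alpha2, phi_bar ul/cm;
# V_transp, k_u1, k_phi cm/h; alpha1 1/h; alpha3 cell/cm;
# delta cm/(h cell); k_u2 cm/cell; k_u3 cell^-2; x_bar_offset cm.
# cell line: sarc
D_u: 0.001
D_phi: 0.0037
chi1: 0.003
chi2: 4.75e-08
V_transp: 0.009
alpha1: 0.154
alpha2: 1e-06
alpha3: 208000
phi_bar: 19.64
delta: 1e-08
k_u1: 2
k_u2: 1e-05
k_u3: 6e-08
k_phi: 0.088
p_crowd: 2
x_bar_offset: 0.004
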