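# Minimal Clb/Cdk1 cell-cycle network, quasi-steady-state (QSSA) core.
# Synthetic reconstruction -- see the package vignette for provenance.
# Free species: x = Clb5/Cdk1, y = Clb3/Cdk1, z = Clb2/Cdk1, s = Sic1.
# Ternary Clb/Cdk1/Sic1 complexes are at quasi-steady state: c_i = K_A*i*s;
# delta degrades Sic1 out of a complex, epsilon degrades the Clb moiety.
x' = v_x - beta_x*x - gamma_yx*y*x - gamma_zx*z*x - epsilon*c_x
y' = v_y + alpha_xy*x + alpha_yy*y - beta_y*y - gamma_yy*y^2 - gamma_zy*z*y - epsilon*c_y
z' = v_z + alpha_xz*x + alpha_yz*y + alpha_zz*z - beta_z*z - gamma_zz*z^2 - epsilon*c_z
s' = v_s - beta_s*s - delta*c_x - delta*c_y - delta*c_z
c_x = K_A*x*s
c_y = K_A*y*s
c_z = K_A*z*s
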