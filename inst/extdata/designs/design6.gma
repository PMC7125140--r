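# Design 3 plus inhibition of SIC1 transcription by all three Clb/Cdk1
# complexes through a shared saturable denominator.
# Synthetic reconstruction -- see the package vignette for provenance.
x' = v_x - beta_x*x - gamma_yx*y*x - gamma_zx*z*x - epsilon*c_x
y' = v_y + alpha_xy*x + alpha_yy*y - beta_y*y - gamma_yy*y^2 - gamma_zy*z*y - epsilon*c_y
z' = v_z + alpha_xz*x + alpha_yz*y + alpha_zz*z - beta_z*z - gamma_zz*z^2 - epsilon*c_z
s' = v_s*K_cs*D_cs^-1 - beta_s*s - delta*c_x - delta*c_y - delta*c_z
c_x = K_A*x*s
c_y = K_A*y*s
c_z = K_A*z*s
D_cs = K_cs + x + y + z
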