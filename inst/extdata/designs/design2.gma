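# Minimal Clb/Cdk1 cell-cycle network with explicit mass-action ternary
# complexes c_i (7 dynamic species). k_on/k_off: complex formation and
# dissociation; delta frees the Clb moiety by degrading Sic1 in a complex,
# epsilon frees Sic1 by degrading the Clb moiety.
# Synthetic reconstruction -- see the package vignette for provenance.
x' = v_x + k_off*c_x + delta*c_x - beta_x*x - gamma_yx*y*x - gamma_zx*z*x - k_on*x*s
y' = v_y + alpha_xy*x + alpha_yy*y + k_off*c_y + delta*c_y - beta_y*y - gamma_yy*y^2 - gamma_zy*z*y - k_on*y*s
z' = v_z + alpha_xz*x + alpha_yz*y + alpha_zz*z + k_off*c_z + delta*c_z - beta_z*z - gamma_zz*z^2 - k_on*z*s
s' = v_s + k_off*c_x + k_off*c_y + k_off*c_z + epsilon*c_x + epsilon*c_y + epsilon*c_z - beta_s*s - k_on*x*s - k_on*y*s - k_on*z*s
c_x' = k_on*x*s - k_off*c_x - delta*c_x - epsilon*c_x
c_y' = k_on*y*s - k_off*c_y - delta*c_y - epsilon*c_y
c_z' = k_on*z*s - k_off*c_z - delta*c_z - epsilon*c_z
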