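# Design 1B plus the Clb3 and Clb2 positive feedback loops (alpha_yy,
# alpha_zz) on their own synthesis.
# Synthetic reconstruction -- see the package vignette for provenance.
x' = v_x + k_off*c_x + delta*c_x - beta_x*x - k_on*x*s
y' = v_y + alpha_xy*x + alpha_yy*y + k_off*c_y + delta*c_y - beta_y*y - k_on*y*s
z' = v_z + alpha_xz*x + alpha_yz*y + alpha_zz*z + k_off*c_z + delta*c_z - beta_z*z - k_on*z*s
s' = v_s + k_off*c_x + k_off*c_y + k_off*c_z + epsilon*c_x + epsilon*c_y + epsilon*c_z - beta_s*s - k_on*x*s - k_on*y*s - k_on*z*s
c_x' = k_on*x*s - k_off*c_x - delta*c_x - epsilon*c_x
c_y' = k_on*y*s - k_off*c_y - delta*c_y - epsilon*c_y
c_z' = k_on*z*s - k_off*c_z - delta*c_z - epsilon*c_z
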