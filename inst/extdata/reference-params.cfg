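# Reference parameterization of the breeding-date reaction-norm model:
# unit variances (all genetic, heritability one), flat-optimum intercept 0,
# optimum slope -1 on nutrition, selection widths 20.
A = 0
B = -1
alpha = 1
omega_y2 = 20
omega_b2 = 20
sigma_n2 = 1
sigma_ai2 = 1
sigma_ei2 = 0
sigma_ab2 = 1
sigma_eb2 = 0
rho_ib = 0
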