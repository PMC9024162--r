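D_ox_gel: 3000.0
D_ox_islet: 2000.0
D_glc_gel: 600.0
D_glc_islet: 300.0
D_ins_gel: 150.0
D_ins_islet: 100.0
alpha_ox: 0.00127
R_ox_max: 0.0356936
K_m_ox: 1.092402
phi_glc_amp: 1.102055
K_phi: 7.133535
n_phi: 2.543032
R_glc_max: 0.0057
K_m_glc: 10.0
S_max: 1.0
K_s: 7.133535
n_s: 2.543032
p_sec_th: 18.575230000000001
sec_width: 36.750399999999999
p_crit: 0.07
delta_smooth: 0.01
k_deg_gel: 0.0
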