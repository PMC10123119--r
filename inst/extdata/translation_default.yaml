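# Default parameters of the ribosome-competition model.
# Units: concentrations nM, time h; eta_plus in 1/nM/h.
model: translation
n_T: 1          # miTarget copy number
n_C: 1          # capacity-monitor copy number
alpha_T: 80.0   # transcription, nM/h per copy
alpha_C: 30.0
alpha_Q: 0.002  # miRNA production, nM/h (free effector is scarce)
beta_T: 0.2     # basal mRNA degradation, 1/h (half-life ~3.5 h)
beta_C: 0.2
beta_Q: 0.3     # miRNA turnover, 1/h
lambda_TQ: 20.0 # fold-increase of miRNA-enhanced degradation (>1)
gamma_T: 2.0    # translation, 1/h
gamma_C: 2.0
delta_T: 0.08   # protein dilution/degradation, 1/h
delta_C: 0.08
kappa_T: 100.0  # effective ribosome-mRNA dissociation constant, nM
kappa_C: 100.0
eta_plus: 1.0   # miRNA binding constant, 1/nM/h
eta_minus: 1.0  # complex dissociation, 1/h
sigma: 1        # 1 = 3'UTR target sites, 0 = 5'UTR
r_total: 1000.0 # total ribosome pool, nM
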