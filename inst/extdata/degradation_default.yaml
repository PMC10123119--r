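# Default parameters of the finite-RNase degradation model.
# Units: concentrations nM, time h; association constants in 1/nM/h.
# Calibrated to an hours-scale endogenous mRNA half-life without miRNA
# regulation and a strongly transcribed, long-lived reporter transcript.
model: degradation
n_T: 1            # miTarget copy number
n_E: 1            # endogenous-gene copy number
alpha_T: 100.0    # miTarget transcription, nM/h per copy
alpha_E: 10.0     # endogenous transcription, nM/h per copy
alpha_Q: 0.025    # miRNA production, nM/h (free effector is scarce)
beta_Q: 0.5       # free-miRNA turnover, 1/h
eta_plus: 0.0     # miRNA binding constant, 1/nM/h (0 = control)
eta_minus: 1.0    # miTarget:miRNA dissociation, 1/h
betaT_assoc: 5.5e-4  # RNase association, free miTarget mRNA (stable reporter)
betaTQ_assoc: 0.4    # RNase association, miRNA-bound miTarget mRNA
betaE_assoc: 2.1e-3  # RNase association, endogenous mRNA
betaT_dissoc: 1.0    # complex dissociation, 1/h
betaE_dissoc: 1.0
betaT_cat: 5.0       # catalytic completion, basal miTarget complexes, 1/h
betaTQ_cat: 0.5      # catalytic completion, miRNA-delivered complexes, 1/h
betaE_cat: 1.0       # catalytic completion, endogenous complexes, 1/h
z_total: 250.0       # total RNase pool, nM
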