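# mirburden

Resource-aware modelling of miRNA-mediated gene expression burden in
mammalian cells.

When two transgenes share a cell, they also share its post-transcriptional
machinery. `mirburden` models what happens when a microRNA downregulates
one of them: the ribosomes and RNA-degradation enzymes (RNases) that the
silenced gene releases are redistributed onto everything else, so a
co-expressed *capacity monitor* gene goes **up** whenever the miRNA
*target* goes **down** — more strongly with more miRNA target sites (TS),
and more strongly with 5'UTR than 3'UTR placement. The package is aimed at
synthetic biologists designing miRNA-regulated circuits (sensors, cell
classifiers, incoherent feed-forward burden mitigators) who need to
anticipate this hidden coupling.

## The models

**Ribosome competition.** A two-gene mass-action ODE system (target mRNA
m_T, target:miRNA complex m_Q, monitor mRNA m_C, free miRNA q, proteins
p_T, p_C; nM and hours). The miRNA binds free target mRNA (rate constant
η⁺), the bound complex is degraded at the enhanced rate
β_T^Q = λ_T^Q·β_T, and the miRNA is recycled. A fixed ribosome pool
r^Total partitions over transcripts by competitive loading; the binary
switch σ encodes TS location (σ = 0: 5'UTR, the complex is sterically
blocked from ribosomes; σ = 1: 3'UTR, the complex is translated). The
steady state has closed form: with dimensionless demand coefficients
ρ_T, ρ_T^Q, ρ_C,

    p̄_T = (γ_T/δ_T) · (ρ_T + σρ_T^Q)/(1 + ρ_C + ρ_T + σρ_T^Q) · r^Total
    p̄_C = (γ_C/δ_C) ·  ρ_C          /(1 + ρ_T + σρ_T^Q + ρ_C) · r^Total
    r̄   = r^Total   /(1 + ρ_T + σρ_T^Q + ρ_C)

miRNA regulation lowers the total target demand ρ_T + ρ_T^Q, which raises
r̄ and hence every other gene's output. The number of TS is proxied by
scaling η⁺ proportionally.

**Finite-RNase degradation.** The second model makes mRNA decay enzymatic:
free RNase binds mRNA into degrading complexes, catalytic completion
consumes the mRNA and releases the enzyme (and the miRNA, for complexes
formed from miRNA-bound mRNA). Strong miRNA slicing sequesters the
machinery in slowly resolving target complexes, producing a *queueing
effect*: after halting transcription, endogenous transcripts decay more
slowly than control, and above a threshold binding constant the decay is
biphasic — nearly flat while the target monopolises the RNases, then fast
once the target pool is exhausted.

On top of the two models sit: stiff steady-state integration (Radau,
atol 1e-9 / rtol 1e-6, 0–10000 h), η⁺ sweeps, transcription-halt decay
experiments, a BIC-based biphasic-phase detector with half-life
estimation and threshold bisection, and `fit_foldchange()` — a
differential-evolution fit of selected model parameters to five-condition
reporter fold-change data under the ridge loss
L(θ) = ‖y − ŷ‖² + λ‖θ‖² (λ = 0.001), plus a seeded synthetic-data
generator for parameter-recovery studies.

## Worked example

Steady state of the translation model with 5'UTR target sites at a
binding constant of 25 /nM/h, using the shipped defaults:

```r
library(mirburden)
p <- translation_params()
steady_state(set_params(p, sigma = 0, eta_plus = 25))
#> Analytic steady state (nM)
#>   proteins:  p_T = 1.224e+04, p_C = 7653
#>   free ribosomes: r = 204.1
#>   densities: miTarget = 1.975, monitor = 2.041 ribosomes/transcript
#>   RNA: m_T = 240, m_Q = 8, m_C = 150, q = 0.006667
```

Against the unregulated control (`eta_plus = 0`: p_C = 5769 nM,
r = 153.8 nM) the monitor and the free-ribosome pool are both up ~33% —
the redistribution effect. Fitting the model back to synthetic
five-condition fold-change data generated at known parameters:

```r
y <- generate_synthetic_foldchanges(eta_unit = 25, noise_cv = 0, seed = 42)
fit <- fit_foldchange(y, seed = 1)
fit
#> Resource-competition model fit to five-condition fold-change data
#>   loss = 0.00118823 (lambda = 0.001), 133 DE iterations
#>   coefficients:
#>    eta_unit   lambda_TQ kappa_ratio
#>    24.73800    20.62300     0.99835
```

The generating truth was (25, 20, 1): recovery within ~3% on noiseless
data (the residual bias is the ridge penalty). `summary(fit)` tabulates
observed vs fitted fold changes; `plot(fit)` draws them.

The queueing effect, as an in-silico transcription-inhibition chase on the
degradation model:

```r
dp <- degradation_params()
profs <- transcription_halt_decay(dp, eta_plus_values = c(0, 4),
                                  species = "endogenous")
half_life(profs[[1]])           # control: 3.38 h
half_life(profs[[2]], extrapolate = TRUE)  # eta+ = 4: 8.07 h
detect_decay_phases(profs[[2]])
#> Biphasic decay: slopes -0.08272 then -0.1849 /h, break at 8 h (delta BIC 315.2)
biphasic_threshold(dp)          # ~3.3 /nM/h: onset of the biphasic regime
```

A thin command-line wrapper ships in `inst/exec/mirburden`
(subcommands `analytic`, `simulate`, `sweep`, `decay`, `fit`,
`make-synthetic`; YAML parameter/config files under `inst/extdata/`).

See `vignettes/resource-aware-mirna-model.Rmd` for the full model
derivations, parameter rationale, and numerical-protocol details.

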