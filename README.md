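# focikinetics

Quantitative analysis of the disappearance of radiation-induced 53BP1 foci
after targeted ion-microbeam irradiation of cell nuclei.

DNA double-strand breaks recruit large aggregates of repair proteins
(53BP1 among them) that are countable as fluorescent foci.  When every
nucleus receives a fixed number of single ions — here five, aimed at the
corners and centre of a 4 µm square — the time course of the mean focus
count per nucleus carries information about how fast the damage is
repaired and how much of it persists.  Two complications stand between the
raw counts and the repair parameters: ions delivered close together
produce foci that cannot be resolved as separate, and the counting system
can deliver zero or two ions when it registers one.  This package
implements the full analysis chain for that setting, for radiation
biologists fitting focus-decay data and for methodologists studying the
estimator itself.

## The model

A Monte Carlo simulation of the irradiation geometry (Gaussian beam
scatter of FWHM 4 µm about the target pattern, ion miscounting, elliptical
nucleus cross-sections with sampled half-axes and orientation,
single-linkage proximity clustering of the traversals inside the nucleus)
yields, per radiation quality Q, the mean number k̄_Q(nᵢ) of clusters of
nᵢ tracks per nucleus.  The observed mean focus count is then

    m_Q(t)   = m_s(t) + m_{r,Q}(t)
    m_s(t)   = n̄_b + n̄_s e^{−β₀(t−t_M)}
    m_{r,Q}(t) = Σ_{nᵢ} P_Q(t|nᵢ) k̄_Q(nᵢ)
    P_Q(t|nᵢ) = 1 − exp{−nᵢ n̄_Q [(1−p_Q) e^{−β₁(t−t_M)} + p_Q e^{−β₂(t−t_M)}]}

with background mean n̄_b, sham-induced mean n̄_s (repair rate β₀),
per-track focus mean n̄_Q at the reference time t_M = 0.5 h, persistent
fraction p_Q (repair rate β₂; normal foci repair at β₁).  P_Q is the
Poisson void probability of a thinned per-cluster focus count: a cluster
is scored as one focus while at least one of its foci survives.  An
equivalent parameterization replaces (n̄_Q, p_Q) by the mean number of
persistent foci per track p̄_Q = n̄_Q·p_Q.

All parameters are estimated by simultaneous weighted nonlinear least
squares over every radiation quality plus the sham series (weights
1/sd², multi-start bounded Levenberg–Marquardt, Jacobian-based standard
errors), with a robustness protocol: start-value sweeps, constraint
variants (β₀ = β₁, β₂ = 0, per-quality β₁, both parameterizations,
independent difference fits), and propagation of the Monte Carlo spread of
k̄_Q through batches of simulated irradiations.  A per-nucleus generative
simulator with exactly the model's Poisson structure serves as oracle and
parameter-recovery testbed.

## Worked example

```r
library(focikinetics)

params  <- default_kinetics_params()          # reference study conditions
qs      <- params$qualities$quality
spectra <- purrr::map2_dfr(qs, 101:104, function(q, s)
  estimate_cluster_spectrum(q, n_nuclei = 5000, seed = s))

design <- experiment_design()                 # 5 times x 3 dishes x 1000 nuclei
dat    <- generate_foci_tables(design, params, spectra,
                               include_control = FALSE, seed = 42)
fit    <- simultaneous_fit(dat, spectra, seed = 7)
glance(fit)
tidy(fit)
```

The proton spectrum says an average nucleus intercepts 2.72 isolated
tracks, 0.57 two-track clusters and 0.15 three-track clusters per
irradiation — the miscounting and beam spread make the rest.  The fit
output (13 parameters, 25 points, f = 12):

```
  chisq    df chisq_per_df n_obs n_par n_starts n_converged
   7.10    12        0.592    25    13       18          18

   term           estimate std.error
   n_b              0.237     0.0134
   n_s              0.305     0.0194
   beta0            0.381     0.0435
   beta1            0.251     0.0150
   beta2            0         0.0116   (at boundary)
   n_protons_3MeV   0.365     0.0111
   n_alpha_20MeV    0.625     0.0145
   n_alpha_10MeV    1.08      0.0220
   n_alpha_8MeV     1.65      0.0327
   p_protons_3MeV   0.150     0.0403
   p_alpha_20MeV    0.0922    0.0267
   p_alpha_10MeV    0.0810    0.0243
   p_alpha_8MeV     0.0860    0.0243
```

Every generator truth (n̄_Q = 0.37/0.63/1.08/1.66, p_Q = 0.17/0.10/
0.11/0.11, β₁ = 0.27/h) is recovered within about two standard errors;
χ²/f ≈ 0.6 says the weighted residuals are consistent with the
between-dish variability.  `render_report(fit)` reshapes this into a
per-quality table with LET metadata and the derived p̄_Q column marked,
`autoplot(fit)` overlays the fitted curves on the data, and
`variant_sweep()` / `spectrum_batch_sweep()` / `start_value_sweep()` run
the robustness protocol.  A YAML-driven `run_pipeline()` ties the stages
together (see `inst/extdata/example-pipeline.yaml`).

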