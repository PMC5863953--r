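# dyadtrack

Simulation and analysis of dyadic haptic interaction during continuous
tracking. Two people track the same moving target with wrist
flexion–extension while their wrists are joined by a virtual elastic band
(hard *K* = 17.2, medium 1.7 or soft 0.3 Nm/rad). Measured against solo
baselines, the worse partner improves more the stiffer the band, while the
better partner is not hindered but spends extra muscular effort. `dyadtrack`
implements the computational framework that explains this pattern, and the
full statistical pipeline used to compare candidate interaction strategies
against trial data.

## The model

Each simulated subject is a linear-quadratic-Gaussian tracking agent:

* Target: a multi-sine waveform
  `t(τ) = −7.8 sin(0.12τ) + 1.6 sin(0.28τ) + 9.4 sin(0.37τ) − 10.6 sin(0.64τ)`
  (degrees, rad/s), displayed as a 10-spot cloud refreshed every 0.4 s
  whose spread σ_t is the subject's visual noise — the "skill" knob.
* Plant: `I θ̈ = u + F`, explicit discrete update at dt = 5 ms; `F = K(θ̃ −
  θ) + D(θ̇̃ − θ̇)` is the elastic coupling torque.
* Estimation: an iterative Kalman filter over an internal target model with
  random-walk velocity (diffusion σ²_μ); control `u = −[L_p, L_v] (θ̂ −
  t̂)` with the infinite-horizon discrete LQR gain minimizing
  `Σ xᵀ(qQ)x + uᵀRu`.
* Interaction strategies:
  * **follow the leader** — the observation switches to the partner's wrist
    (read off the spring force) whenever it is nearer the target;
  * **interpersonal goal integration** — the partner's feedback gains
    `[L̃_p, L̃_v]` are identified from the interaction force by an extended
    Kalman filter, the partner's goal t̃ is inferred, and it is fused with
    one's own visual estimate weighted by the partner's visual variance
    σ̃²_v;
  * **neuromechanical goal sharing** — the same fusion, but the haptic
    channel variance is inflated by a stiffness-dependent term σ²_s(K)
    calibrated from a haptic-only tracking condition (target invisible,
    sensed only through the spring).
* Metrics per solo/connected trial pair: improvement `Δc = 1 − e_c/e`,
  relative error `Δp = 1 − e_p/e`, interaction effort `E = α_c/α − 1`.
* Statistics: maximum-likelihood mixed models `Δc ~ Δp + κ + Δp² + Δp·κ +
  Δp²·κ + (1 | dyad)` and `E ~ Δp + κ + Δp·κ + (1 | dyad)` with
  likelihood-ratio model comparison, repeated-measures ANOVA with Mauchly's
  test and Greenhouse–Geisser correction, Tukey–Kramer post-hocs and
  Bonferroni one-sample t-tests.

## Worked example

```r
library(dyadtrack)

# a skilled and an unskilled subject
a1 <- agent_spec(sigma_v_deg = 1.5)
a2 <- agent_spec(sigma_v_deg = 4.5)
traj <- generate_target(seed = 1)   # 40 s multi-sine, random phase

run_solo(a2, traj, seed = 2)
#> <trial_result> 8001 samples; RMS error 4.243 deg; effort 0.001543 Nm

# hard coupling under neuromechanical goal sharing
nm <- calibrate_haptic_noise(seed = 1)
nm$sigma_s2
#>       hard     medium       soft
#>  0.0000000  0.1114659 11.0917327     # deg^2
tr <- run_dyad(a1, a2, coupling_spec(17.2), traj,
               strategy = "neuromechanical", seed = 2,
               sigma_s2_deg2 = nm$sigma_s2[["hard"]])
tr$agent2
#> <trial_result> 8001 samples; RMS error 3.488 deg; effort 0.5512 Nm
```

The unskilled subject's error drops from about 4.2° solo to about 3.5°
when rigidly coupled to the skilled partner (an improvement Δc ≈ 0.18),
while the torque spent rises by the cost of working against the spring —
the qualitative signature the framework is built to reproduce. A full
synthetic experiment (45 trials × 14 dyads, block schedule, pairing and
statistics) is one call:

```r
gd <- generate_dyad_dataset(n_dyads = 14, strategy = "neuromechanical",
                            seed = 1, noise_model = nm)
st <- run_statistics(gd$paired)
st$improvement_stiffness_lrt
#> <test_report> likelihood ratio: statistic = 15.73, df = 3, p = 0.00129
```

`reproduce_study()` chains every stage (calibration, three strategy
populations, metrics, statistics, sensitivity grid) into a manifest with
pass/fail trend checks, and accepts the published trial-pair and
haptic-tracking text files when available.

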