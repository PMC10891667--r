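# gaitinit

Gait-initiation center-of-mass kinematics and between-system agreement.

## What this is for

Gait initiation — the transient between quiet standing and steady-state
walking — is commonly summarized by two whole-body center-of-mass (COM)
velocity indicators:

* **Motor performance** `MP = max vx(t)`: the peak anteroposterior COM
  velocity, an index of propulsion capacity;
* **Braking index** `BI = (Vzmin − VzFC) / Vzmin`: the fraction of the peak
  downward vertical COM velocity (`Vzmin`) cancelled before swing-foot
  contact (`VzFC` = vertical velocity at contact). `BI = 1` is a fully
  braked, soft landing; `BI ≈ 0` a passive fall onto the foot, typical of
  Parkinsonian gait.

Two measurement chains estimate the same COM velocity at 85 Hz:

* **Force-plate system (FPS, gold standard)** — two plates in series; forces
  summed; Newton's second law (`az = (Fz − m g)/m`, `ax = Fx/m`); single
  left-rectangle integration with null initial velocity;
* **Markerless system (MLS)** — a COM position trajectory differentiated by
  backward finite differences, `v(t_k) = (p(t_k) − p(t_{k−1}))·fs`.

Both chains apply a no-lag (zero-phase) 15 Hz low-pass Butterworth filter.
The package is aimed at movement scientists who want to test whether the
markerless chain can stand in for the force-plate chain: it implements both
chains, the indicator extraction, a physics-consistent synthetic cohort
generator with analytically known ground truth, and the agreement battery —
Bland–Altman 95% limits of agreement (absolute and relative), a paired JZS
Bayes factor 01 with a Cauchy-prior robustness curve, and a mixed-design
repeated-measures ANOVA (group between; velocity condition and system
within) with Tukey post hoc contrasts.

## Worked example

```r
library(gaitinit)

cfg <- sim_config(master_seed = 42)

# one trial with known truth, run through both chains
trial <- simulate_trial(cfg, trial_meta("YH01", "YH", "MVC", 1, mass = 70),
                        seed = 42, bi_true = 0.75, mp_true = 1.8)
extract_indicators(trial, "FPS")
#> <gi_indicators> FPS | BI 0.736 (Vzmin -0.339, VzFC -0.090 m/s) | MP 1.799 m/s @ 1.753 s
extract_indicators(trial, "MLS")
#> <gi_indicators> MLS | BI 0.754 (Vzmin -0.332, VzFC -0.082 m/s) | MP 1.795 m/s @ 1.753 s
```

Both chains recover the configured truth (BI 0.75, MP 1.8 m/s) to within a
few hundredths despite 2 N force noise and 2 mm positional drift.

```r
# the full study design: 3 groups x 2 conditions x 10 participants x 5 trials
cohort <- simulate_cohort(cfg)
tab <- indicator_table(cohort)          # 600 rows: 300 trials x 2 systems
fps <- tab[tab$system == "FPS", ]; mls <- tab[tab$system == "MLS", ]

jzs_bf01_paired(fps$bi, mls$bi)
#> <gi_bf> BF01 = 14.758 (BF10 = 0.068) | t = -0.304, n = 300, Cauchy r = 0.707
#>   strong evidence for H0
#>   robustness: BF01 in [2.594, 41.488] over r in [0.10, 2.00]
```

`BF01 = 14.8 > 3`: the trial-wise braking-index differences between the two
systems support the null hypothesis of no between-system difference.

```r
mixed_anova(tab, "mp")
#> <gi_anova> dv = mp, unit = participant_mean
#>   group                     F(2, 27) =   84.904, p = 2.259e-12
#>   velocity                  F(1, 27) =  279.852, p = 8.926e-16
#>   group:velocity            F(2, 27) =    5.102, p = 0.0132
#>   system                    F(1, 27) =    1.670, p = 0.2072
#>   ...
```

Motor performance shows the designed group and velocity effects, and no
system effect — both chains detect the same physiology.

```r
bland_altman(fps$bi[fps$group == "PD"], mls$bi[mls$group == "PD"],
             stratum = c("PD", "all"))
#> <gi_bland_altman> [PD all] n = 100
#>   bias -0.0016, SD 0.0137, 95% LoA [-0.0284, 0.0253]
#>   relative: bias -0.45%, LoA [-7.63%, 6.74%]
#>   Shapiro-Wilk W = 0.9888, p = 0.5702
```

Near-zero bias; `reliability_verdict()` applies the 10% rule to the relative
limits.

## Command-line workflow

```sh
Rscript -e 'quit(status = gaitinit::gi_cli())' --args simulate --out trials --seed 7
Rscript -e 'quit(status = gaitinit::gi_cli())' --args indicators --in trials --out indicators.csv
Rscript -e 'quit(status = gaitinit::gi_cli())' --args agree --in indicators.csv --out agree
Rscript -e 'quit(status = gaitinit::gi_cli())' --args report --in indicators.csv --out report
```

Every run writes a manifest with the master seed and a config hash, so any
output is reconstructible from `(config, seed)`.

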