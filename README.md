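# swinesim

An agent-based, daily-timestep simulator of growing-finishing pigs
(20 → 130 kg) implementing the 2012 Swine NRC equation set: individual
stochastic body-weight gain, body composition (protein, lipid, water,
ash), metabolizable energy and feed intake with thermal-environment
effects, and the full daily nutrient-requirement chain — SID lysine and
the essential amino acids, STTD phosphorus, calcium, and log-linear
mineral/vitamin requirements. It is written for swine nutritionists,
production modellers, and students who want a reproducible *in silico*
herd: every pig is an agent with its own RNG substream, so runs are
bit-reproducible and replications are statistically independent.

## The model in brief

Per pig and day *i* (sex-specific coefficients for gilts, barrows,
boars):

| quantity | equation |
|---|---|
| gain (g/d) | `BWG = 485.17 + 8.8503·BW − 0.0477·BW²`, daily draw `N(BWG, (cv·BWG)²)` floored at 0 |
| weight (kg) | `BW_i = BW_{i−1} + BWG/1000` |
| protein deposition (g/d) | `Pd = a(b + c·BW + d·BW² + e·BW³)` |
| energy intake (kcal/d) | `MEI = a{1 − exp[−eᵇ·BW^c]}` |
| maintenance (kcal/d) | `mME = 197·BW^0.6 + 0.07425·(LCT − T)₊·StdmME + adj`, `LCT = 17.9 − 0.0375·BW` |
| lipid deposition (g/d) | `Ld = (MEI − mME − 10.6·Pd)/12.5` |
| SID lysine (g/d) | `[GIT + integument losses + 0.071·Pd·(1.0547 + 0.002215·BW)] / [0.75 + 0.002(Pd_max − 147.7)]` |
| STTD P, Ca (g/d) | `0.85[ret/0.77 + 0.19·FDMI + 0.007·BW]`, `Ca = 2.15·STTD P` |
| minerals/vitamins | `p + q·ln BW`, fitted from the published day-130 reference points |

Amino acids are fixed ratios of SID lysine (threonine 60.3%, valine
64.9%, ...). Pigs are removed on the day they reach target weight,
after that day's record; 140 days is a hard stop. See
`vignettes/swinesim-methods.Rmd` for assumptions, open design points,
and limitations.

## Worked example

```r
library(swinesim)
cfg <- herd_config(n_pigs_per_sex = 4, n_replications = 50)
run <- run_replications(cfg)
run
#> <sns_run> 50 replication(s), 600 pigs, 80734 record rows, 138 day(s)

summarize_replications(run, "bw")[day == 130]
#>       sex variable   day     n     mean       sd   ci_low  ci_high
#> 1: barrow       bw   130   200 127.4988 1.444091 127.2987 127.6989
#> 2:   boar       bw   130   200 127.3030 1.374023 127.1126 127.4934
#> 3:   gilt       bw   130   198 127.5221 1.221137 127.3521 127.6922
```

Mean day-130 weight is ~127.5 kg (the published reference mean is
126.55 kg for gilts; the simulator lands within 1%). `n = 198` for
gilts because two of the 200 pooled gilts crossed 130 kg early and were
marketed. The day-130 requirement snapshot reproduces the published
report layout:

```r
requirements_snapshot(run, day = 130)
#>               section    quantity units    gilt  barrow    boar
#>                growth          bw    kg 127.522 127.499 127.303
#>           amino_acids  sid_lysine   g/d  16.480  15.828  18.678
#>           amino_acids   threonine   g/d   9.937   9.544  11.263
#>    phosphorus_calcium      sttd_p   g/d   5.783   5.475   6.843
#>    phosphorus_calcium    total_ca   g/d  12.433  11.772  14.713
#>               mineral      sodium   g/d   2.933   2.933   2.931
#>               vitamin vitamin_b12  ug/d  12.503  12.503  12.505
#>  ... (24 mineral/vitamin rows)
```

SID lysine orders boar (18.7) > gilt (16.5) > barrow (15.8) g/d, as the
published day-130 report does (19.47 > 17.65 > 17.31), and calcium is
exactly 2.15 × STTD P. The verification harness regresses stochastic
pig-days on the deterministic reference trajectory:

```r
verify_run(run, variables = "bwg")
#>       sex variable r_squared     slope intercept     n
#> 1: barrow      bwg 0.7548601 0.9955667  4.067807 26602
#> 2:   boar      bwg 0.7558103 1.0019136 -1.579157 26643
#> 3:   gilt      bwg 0.7518703 0.9917526  7.179185 26620
```

Slope ≈ 1 and intercept ≈ 0: the noise is unbiased around the reference
equations. r² depends on the gain CV (1.0 at zero noise, ~0.83 at
CV = 0.04, ~0.75 at the default 0.05); the vignette discusses the
calibration band around the published 0.84–0.93.

Deterministic single-pig runs, config files, and file export:

```r
det <- deterministic_trajectory(herd_config(), "gilt")
det$bw[det$day == 130]      # 127.2647 kg
cfg <- load_config("my_run.json")   # flat JSON, unknown keys fail loud
export_results(run, "out/")  # records/summary/verification CSVs + meta JSON
```

Command line (writes the same file set):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","simulate.R",package="swinesim"))')" \
  --config my_run.json --seed 7 --replications 500 --out out/
```

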