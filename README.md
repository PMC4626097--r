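# atrophynet

Network-diffusion modeling of regional gray-matter atrophy on structural
brain connectomes, for researchers studying how focal pathology — the
motivating case is temporal lobe epilepsy (TLE) — produces distributed,
stereotyped atrophy along white-matter connections.

Two competing mechanisms are implemented as linear diffusion models on the
symmetric normalized Laplacian
`L = I − Δ^{−1/2} C Δ^{−1/2}` of a weighted connectome `C` with degrees
`δ_i = Σ_j c_ij`, eigenvalues `0 = λ1 < λ2 ≤ … ≤ λN ≤ 2` and eigen-modes
`u_i`:

* **Model 1 — spread of activity (excitotoxicity).** Atrophy is the
  lifetime integral of diffusing epileptogenic activity from a seed `x0`:
  `Φ1 = Σ_{i=2..K} (1/λ_i) u_i (u_i' x0)` — a partial eigen-mode expansion
  of the Laplacian pseudo-inverse. Free parameter: the mode count `K`.
* **Model 2 — spread of atrophy (progressive degeneration).** Atrophy is
  the running integral of a diffusing degenerative front from seed `y0`:
  `Φ2(t) = Σ_{i=2..N} ((1 − e^{−λ_i t})/λ_i) u_i (u_i' y0)`. Free
  parameters: the seed region and the diffusion depth `t_crit`.

Model 1 is exactly Model 2 at `t = ∞`, so the shape of the correlation
curve `R(t)` — peaked at intermediate depth versus monotone increasing —
discriminates the mechanisms. Measured atrophy is the per-region Welch
two-sample t-statistic between healthy controls and patients, after
mirroring right-focus patients onto a common ipsilateral hemisphere.
Significance is assessed with permutation nulls that re-optimize the free
parameter inside every shuffle. A synthetic bilateral connectome and
cohort generator validates the whole pipeline end-to-end with planted
ground truth.

## Worked example

Generate an 86-region synthetic connectome and a 30 healthy / 50 patient
cohort with Model-2 atrophy planted at the left hippocampus (`t = 5`),
then run the full analysis:

```r
library(atrophynet)

spec   <- synthetic_spec(n_healthy = 30, n_patient = 50)
conn   <- make_connectome(spec, rng_seed = 7)
eig    <- laplacian_eigensystem(conn)
cohort <- make_cohort(spec, conn, rng_seed = 8)

measured <- measure_atrophy(side_flip(cohort, conn$atlas), conn$atlas)
#> atrophy_vector: 86 regions, t-stats in [-3.54, 15.5], groups n=30/m=50

fit1 <- fit_model1(eig, bilateral_temporal_seed(conn$atlas), measured)
#> fit_result [model1]: R = -0.1244 (p = 0.254), K=53

fit2 <- fit_model2(eig, measured)
fit2$best
#> fit_result [model2]: R = 0.8594 (p = 3.38e-26),
#>   seed_region=34, seed_name=Hippocampus-L, t_crit=4.56

classify_curve(fit2$best$curve)
#> [1] "peak_at_intermediate_t"

permutation_null_model2(eig, fit2$best$param$seed_region, measured,
                        n_iter = 1000, rng_seed = 9)
#> null_distribution: observed R = 0.8594, 0/1000 permutations exceed
#>   (0.0000; add-one p = 0.0010)
```

Reading the numbers: the per-seed sweep singles out the true planted seed
(`Hippocampus-L`) with `R = 0.86` at a depth (`t_crit ≈ 4.6`) close to the
planted `t = 5`; the `R(t)` curve peaks at an intermediate depth, so the
degenerative-spread mechanism is (correctly) declared the better model;
and none of 1000 re-optimized permutations of the atrophy map reach the
observed correlation. The activity model, seeded bilaterally in the
temporal lobes, fails to explain this hippocampus-seeded pattern
(`R ≈ −0.12`). The top of the per-seed table shows the expected
neighborhood structure — adjacent subcortical seeds fit far worse than
the true one:

```r
head(fit2$table[order(-fit2$table$R), ], 3)
#>    region_id          name     t_crit         R     flag
#> 35        34 Hippocampus-L   4.560623 0.8594253   global
#> 38        37         VDC-L 500.000000 0.4217704 monotone
#> 39        38     Putamen-L 160.614545 0.3774610   global
```

## Command line

A plain-text `key = value` config drives the same pipeline:

```sh
cat > config.txt <<EOF
out_dir = run1
rng_seed = 7
n_healthy = 30
n_patient = 50
EOF
Rscript -e 'atrophynet::main()' simulate config.txt   # writes dataset + truth sidecar
cat > fit.txt <<EOF
connectome = run1/connectome.txt
atlas = run1/atlas.tsv
volumetrics = run1/volumetrics.tsv
out_dir = run1
n_iter = 1000
EOF
Rscript -e 'atrophynet::main()' fit  fit.txt          # tables + summary.txt
Rscript -e 'atrophynet::main()' null fit.txt          # permutation nulls
```

Every run writes a `manifest.txt` (config echo, package version, seeds)
sufficient to reproduce its outputs exactly.

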