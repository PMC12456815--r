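# tadwalk

Random-walk smoothing — random walk with a small number of steps (RWS) and
random walk with restart (RWR) — is a popular preprocessing step for sparse
Hi-C and single-cell Hi-C contact matrices. Whether it actually *helps* the
downstream task it is meant to help, such as finding topologically
associating domains (TADs), is a quantitative question. `tadwalk` is an R
package for asking it: it generates contact matrices with known TAD
structure, smooths them, calls domains, and measures how much of the truth
survives.

It is aimed at methodologists evaluating Hi-C imputation pipelines and at
practitioners deciding whether (and with which tuning parameters) to smooth
before TAD calling.

## What the package computes

A symmetric contact matrix `M` is balanced with the **Knight–Ruiz (KR)
algorithm** into a symmetric doubly stochastic transition probability matrix
`P = diag(x) M diag(x)` (all-zero rows get a unit diagonal first). Two
smoothing families are then available:

- **RWS**: the s-step transition matrix `P^s`. For an irreducible chain
  `P^s → J/N` as `s → ∞` — every entry equal, all domain structure erased.
- **RWR**: the restart recursion `P(s) = (1−α) P(s−1) P + α I`, `P(0) = I`,
  with closed-form limit `P* = α (I − (1−α) P)^{-1}`. For the idealized
  block TPM (within-block entries `(1 − (N−n_i)d)/n_i`, between-block
  entries `d`) the limit has the explicit block form `α I + q_i J` with
  `q_i = (1−α)(d + α(1−Nd)/n_i) / (α + (1−α)Nd)`, so its dominant feature
  is the main diagonal, not the blocks.

Detected partitions (from the built-in insulation-style caller, degenerate
baseline callers, or any user-supplied caller) are compared to the truth
with the **Hubert–Arabie adjusted Rand index (ARI)**. Three replicated study
designs wrap this up: an idealized noisy TPM, a power-decay negative-binomial
count simulator with planted domains, and multinomial subsampling of a bulk
matrix down to single-cell-like sparsity.

## Worked example

```r
library(tadwalk)

# Idealized 200-locus matrix with 5 TADs, uniform noise, KR, RWS/RWR grids:
spec <- ideal_spec(N = 200, block_sizes = c(50, 30, 20, 90, 10), d = 0)
report <- run_study1(spec, callers = default_callers(), seed = 1)
report
#> <rw_eval> study1 | 1 replicate(s) | 12 condition(s)
#> # A tibble: 12 × 2
#>    condition insulation
#>    <chr>          <dbl>
#>  1 KR                 1
#>  2 RWR0.05            1
#>  ...
#> 11 ideal              1
#> 12 noisy              1
```

On this easy, nearly noise-free problem every condition scores ARI 1: the
insulation caller recovers all five domains whatever the smoothing. The
realistic simulator separates the conditions:

```r
# Power-decay counts, 1000 loci, 20 random domains, structured zeros:
rep2 <- run_study2(biophysical_spec(N = 1000, k = 20), n_reps = 10, seed = 1)
median_ari(rep2)
#> # A tibble: 11 × 3
#>    condition caller     median_ari
#>  1 KR        insulation      0.564
#>  2 RWR0.05   insulation      0.642
#>  3 RWR0.1    insulation      0.639
#>  4 RWR0.2    insulation      0.626
#>  5 RWR0.5    insulation      0.608
#>  6 RWS10s    insulation      0.230
#>  7 RWS2s     insulation      0.799
#>  8 RWS3s     insulation      0.656
#>  9 RWS4s     insulation      0.454
#> 10 RWS5s     insulation      0.394
#> 11 count     insulation      0.633
```

Read: a two-step walk helps a little here (0.80 vs 0.63 on raw counts), but
accuracy collapses as steps grow (0.23 at ten steps), and the RWR limit is
nearly flat in the restart probability α — there is no signal in that tuning
knob. `autoplot(rep2)` draws the per-condition ARI distributions as violins;
`plot_contact_matrix(M)` shows any matrix with its domain boxes.

`subsample_counts()` and `sparsity_sweep()` extend the same comparison to
single-cell-like subsamples of a bulk matrix across sampling rates, and
`write_matrix()` / `read_matrix()` move matrices through dense-TSV or
upper-triangle COO text.

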