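# phenohill

Quantifies the **diversity of phenological patterns** in an ecological
community — how distinctly its species spread their activity (breeding,
flowering, any phenophase measured as an intensity over time) across the
study period — as **phenological Hill numbers** `qPD`, for ecologists
who want a single comparable number (or a profile over the order `q`)
per community.

## The measure

Starting from species-by-time intensity records on a regular grid:

1. **Wavelet smoothing.** Each species' discrete series is smoothed
   into a continuous curve *z_i(t)* by a Morlet continuous wavelet
   transform; the attenuation threshold `tau` (default 2) sets how much
   fine-scale structure survives, and sampling gaps are interpolated in
   the process.
2. **Overlap distances.** Every pair of curves gets a modified
   Morisita–Horn distance

   O_ij = 1 − 2∫z_i z_j dt / (∫z_i² dt + ∫z_j² dt) ∈ [0, 1],

   0 for identical curves, 1 for temporally disjoint ones.
3. **Hill diversity.** With relative intensities p_i = ∫z_i / Σ_j ∫z_j
   and Q = ΣΣ O_ij p_i p_j, the order-q attribute diversity

   qPD = [ ΣΣ (O_ij/Q) (p_i p_j)^q ] ^ {1/(2(1−q))}

   (Shannon-limit form at q = 1) expresses the community as an
   *effective number of phenologically distinct curves*: 0 when all
   curves are identical, S when S equally weighted curves are disjoint,
   with a non-increasing profile in q that is flat exactly when
   intensities are even.

## Worked example

Benchmark case **b** — 40 species whose activity pulses are staggered
evenly across a 360-step period but whose intensities decline
geometrically (ratio 0.9):

```r
library(phenohill)
fit <- phenohill(simulate_case("b"))
fit
#> Phenological Hill numbers
#>   S = 40 species, 360 time points
#>   Q = 0.9458
#>   qPD:  q=0: 40.61   q=1: 24.48   q=2: 18.96
round(predict(fit, q = c(0, 0.5, 1, 1.5, 2)), 2)
#> [1] 40.61 30.39 24.48 21.07 18.96
```

Read: at `q = 0` (intensity ignored) the community behaves like ~40.6
distinct curves — slightly *more* than S = 40 because the mean relative
overlap Q is below 1; weighting by intensity (`q = 1`, `q = 2`) shrinks
that to ~24 and ~19 effective curves, revealing the dominance of the
high-intensity species. Had all 40 pulses been equally intense (case
`"a"`), the profile would be flat at exactly 40; had all curves been
identical (case `"c"`), every `qPD` would be 0. `plot(fit)` draws the
profile; `summary(fit)` adds the distance and weight ranges.

The same analysis runs from a CSV on disk (wide layout:
`time,sp1,sp2,...`), through smoothing, in one call:

```r
res <- run_pipeline("records.csv", "out/", config = smoothing_config(tau = 2))
#> writes out/smoothed.csv, out/dist.csv, out/profile.csv
res$PD          # qPD at q = 0, 1, 2
```

or from a shell via the bundled CLI
(`Rscript $(Rscript -e 'cat(system.file("cli", "phenohill.R", package = "phenohill"))')
run --input records.csv --outdir out`), with subcommands `simulate`,
`smooth`, `distance`, `pd`, `profile`, `run`.

If you have the wavelet-transformed Madagascar amphibian table
(40 species, 120 samples) from the study this measure originates in,
drop it at `inst/extdata/madagascar_wavelet.csv` and run the pipeline
with `skip_smoothing = TRUE` (the file already holds smoothed curves);
the associated test then checks ⁰PD ≈ 47.5, ¹PD ≈ 13, ²PD ≈ 8.4.

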