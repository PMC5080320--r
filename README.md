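# indelphase

Measuring accelerated (or conserved) rates of insertions and deletions
across alignment columns, independently of nucleotide substitution rates.

Conserved regions of proteins and regulatory DNA can be constrained for
length without being constrained for sequence, and vice versa.  Tools built
on substitution models (phyloP and relatives) only see the second kind of
constraint.  `indelphase` implements the complementary measurement for
people studying molecular evolution on sets of gene-family alignments: it
fits a gap-extended substitution model — DNA plus `-` as a fifth evolving
state — across all families at once, and then tests every alignment column
for indel-rate acceleration or conservation with a per-column
likelihood-ratio test.

## The model and the tests

Columns evolve independently on fixed gene trees under a 5-state generator:
an F84 substitution block (transition rate component α, general component
β, empirical frequencies π), deletions residue → `-` at rate μ, insertions
`-` → residue *j* at rate λπ*ⱼ*, and a geometric ancestral-length prior
with parameter *p* that weights each column's root by *p*·π (ancestral
residue) or 1 − *p* (no ancestral residue).  Gaps at leaves are data, not
missing values, and multiple insertions may hit one column — recurrent
indels clumping into a single column are exactly what the test looks for.

Two per-column LRTs (both χ²₁):

| test | null | alternative | score |
|------|------|-------------|-------|
| subst | F84, gaps missing | branch lengths × ρ | phyloP-style |
| indel | F84ε-relaxed fit | μ × ρ_indel, λ × ρ_indel·(D/I) | indelP |

where D/I is the deletion/insertion total-length ratio counted from
ancestral reconstructions by implicit parsimony.  Scores are signed log₁₀
p-values, acceleration positive by default (`--phast-sign` flips).

## Worked example

Simulate a deletion-biased benchmark (50 families x 400 columns on the
10-taxon benchmark tree), fit the gap-extended model, count indel events,
and score every column (~1 minute):

```r
library(indelphase)

bm  <- make_benchmark_set(sim_config(n_families = 50, n_columns = 400,
                                     seed = 7))
fit <- fit_model(bm$aset, "F84E_RELAXED")
fit
#> <ip_fit> F84E_RELAXED logLik -196180.3 (converged)
#>      alpha       beta     lambda         mu          p
#> 0.51509900 0.48528900 0.00316806 0.06063690 0.99750000

ev <- count_indel_events(bm$aset, fit$model)
ev
#> <event_counts> insertions: 2  deletions: 5286  D/I: 2643
di <- if (ev$no_insertions) 1 else ev$di_ratio

scores <- do.call(rbind, lapply(bm$aset, function(p)
  indel_rate_test(p$alignment, p$tree, fit$model, di)))
sum(scores$pvalue < 0.05)      # 554 of 19952 columns nominally significant
bonferroni_alpha(0.05, nrow(scores))   # 2.5e-06
head(scores[order(scores$pvalue), c("family_id", "column", "scale",
                                    "pvalue", "score")], 3)
#>  family_id column scale    pvalue score
#>    fam0022    321 10000 0.0003143 3.503
#>    fam0024    225 10000 0.0003422 3.466
#>    fam0001     88 10000 0.0003783 3.422
```

The fit recovers the generating substitution parameters (α = 0.513,
β = 0.487) and deletion rate (μ = 0.0617) closely; the insertion rate, which
is informed only by the few percent of tree length spent in the gap state,
is the noisiest quantity.  Positive scores are indel-accelerated columns;
none of these reach the Bonferroni threshold, as expected for null data.

The same pipeline runs from the shell:

```sh
inst/cli/indelphase simulate --out-dir data --seed 7 --families 50 --columns 400
inst/cli/indelphase fit      --data data --model F84E_RELAXED --out fit.mod
inst/cli/indelphase count    --data data --model fit.mod --out events.tsv
inst/cli/indelphase score    --data data --model fit.mod --tests indel --out-dir out
```

`out/scores.tsv` carries one row per column
(`family_id column test lnl_null lnl_alt scale pvalue score`) and
`out/summary.json` the significant-site counts at the raw and
Bonferroni-corrected thresholds.

## Layout

* `R/` — trees/alignments I/O and filtering, rate matrices, pruning engine,
  multi-family fitting, per-site tests, ancestral event counting, simulator,
  CLI.
* `vignettes/indel-rate-models.Rmd` — the model, its assumptions, numerical
  choices, and known limitations.
* `tests/testthat/` — unit, property and acceptance suites (enumeration and
  closed-form oracles in `helper-oracles.R`).
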