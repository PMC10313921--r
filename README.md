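# sliceDSS

Multi-parametric drug sensitivity scoring for ex vivo brain-slice drug
screens.

Organotypic brain-slice cultures (OBSCs) let a tumor be treated on living
normal brain tissue, so a screen reads out two curves per drug: tumor
kill (bioluminescence of luciferase-labelled tumor foci, normalized to
day-one size and untreated controls) and normal-tissue toxicity
(propidium-iodide signal, anchored between a healthy baseline and a dead
control). sliceDSS is for labs running such screens — and for anyone with
paired kill/toxicity dose-response tables — who want a single,
comparable, therapeutic-window-aware score per drug–tumor pair rather
than an IC50 that ignores tissue damage.

## The score

All dose-response quantities are computed by **linear interpolation of
the measured points** (log10-dose axis for µM, linear for Gy) — never
from a fitted curve. Eleven therapeutic windows, each on [−1, +1] (+1 =
kill without toxicity, −1 = toxicity without kill), are combined as a
weighted sum on the ±100 scale:

    DSS = 100 · Σ wᵢ · windowᵢ

| window | weight | | window | weight |
|---|---|---|---|---|
| max kill | 10% | | slope through EC50 | 10% |
| EC10 | 5% | | AUC (kill − tox) | 35% |
| EC25 | 5% | | growth acceleration | 5% |
| EC50 | 10% | | biphasic shape | 5% |
| EC75 | 5% | | incomplete kill | 5% |
| EC90 | 5% | | | |

Windows 1–8 compare kill against toxicity (ECx windows at the dose where
tumor kill crosses x%, with a shortfall penalty when the level is not
reached); windows 9–11 score the tumor curve's own behavior (growth
beyond 125%/150% of untreated, biphasic plateaus, >10%/25% residual
tumor). An ECx/IC50 that is never attained within the tested dose range
is reported as **NR** (not reached), never extrapolated.

## Worked example

Simulate the built-in five-scenario pack (sensitive, resistant,
growth-promoted, biphasic, toxic-only) at 10% replicate noise, then score
it end to end:

```r
library(sliceDSS)

td  <- file.path(tempdir(), "demo")
out <- file.path(td, "scored")
runSimulate(td, seed = 1, noiseCv = 0.10)          # writes tumor_raw.csv, slice_raw.csv, truth.json
scored <- runScore(file.path(td, "tumor_raw.csv"),
                   file.path(td, "slice_raw.csv"), out,
                   cohorts = c(SYN1 = "cell_line"))
scored$matrix
#> DssMatrix: 5 drug(s) x 1 tumor(s), 5 score(s), 0 missing
#>            SYN1
#> sensitive    61
#> resistant    -5
#> growth      -55
#> biphasic     13
#> toxic_only  -49
```

The sensitive agent scores +61: it kills the tumor well before the slice
is harmed. The growth-promoted agent scores −55: the treated tumor
outgrows the untreated control while the slice takes damage. Per-pair
window detail:

```r
scored$windows[["SYN1|sensitive"]]
#> TherapeuticWindows [sensitive x SYN1]
#>   max_kill       ec10       ec25       ec50       ec75       ec90      slope
#>      0.827      0.099      0.240      0.491      0.746      0.884      0.520
#>        auc     growth   biphasic incomplete
#>      0.507      1.000      1.000      1.000
```

and the IC50 report (NR where <50% of the tumor died at the top dose):

```r
icxTable(scored$curves, x = 50)
#>   tumor_id    drug_id  x    dose_at_x reached below_range
#> 1     SYN1  sensitive 50 4.720488e-01    TRUE       FALSE
#> 2     SYN1  resistant 50 1.080952e+04    TRUE       FALSE
#> 3     SYN1     growth 50           NA   FALSE       FALSE
#> 4     SYN1   biphasic 50           NA   FALSE       FALSE
#> 5     SYN1 toxic_only 50           NA   FALSE       FALSE
```

`runScore()` also writes `windows.csv`, `icx.csv`, `dss_matrix.csv`
(empty cells for untested drug–tumor pairs), `waterfall.csv` and a
`run_config.json` sidecar with the weights and NR annotations. A thin
command-line wrapper with `score` / `simulate` / `qc` subcommands ships
at `inst/scripts/obsc-dss.R`. Batch-level slice viability QC is available
through `qcBatch()` / `runQc()`.

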