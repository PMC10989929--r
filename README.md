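# chaseterm

Tools for inferring RNA decay kinetics and premature transcription
termination from rifampicin-chase RT-qPCR data and steady-state transcript
intensities.

## The problem

In bacteria with long 5' untranslated regions — the motivating case is the
*rne* gene (RNase E) of the cyanobacterium *Synechocystis*, whose 5' UTR
spans hundreds of nucleotides and is cleaved by RNase E itself — the UTR
segment of a transcript can be far more abundant than the coding segment.
Two very different mechanisms produce that pattern: differential decay and
premature termination of transcription. They can be disentangled with two
routine measurements, because at steady state a transcript level is the
ratio of its synthesis rate to its decay constant:

```
Int = α / λ
```

so the ratio of synthesis rates between segments i and j is

```
FCsynt = αi/αj = (Inti/Intj) × (λi/λj)
```

— the product of an intensity fold change and a decay-constant fold
change. Under a single promoter, a UTR/ORF synthesis ratio above 1 means
polymerases terminate inside the UTR, with termination fraction

```
f = 1 − 1/FCsynt
```

`chaseterm` implements the full chain for this inference:

* **`simulate_chase()`, `simulate_intensity_fc()`,
  `simulate_sequence_with_sites()`** — a seeded generator of chase
  time courses (Ct scale), steady-state intensity fold changes, and RNA
  sequences with planted cleavage signatures, under the
  promoter → termination → decay model.
* **`delta_delta_ct()`** — ΔΔCt relative quantification (efficiency
  exactly 2, technical replicates averaged on the Ct scale, per-series
  calibration at t = 0).
* **`fit_exponential_decay()`, `fit_decay()`, `bootstrap_ci()`** — pooled
  nonlinear least-squares fits of `N0·exp(−λt)` per compartment with
  series-level percentile bootstrap intervals; broom-style `tidy()` /
  `glance()` and `autoplot()` methods.
* **`synthesis_ratio()`, `termination_fraction()`, `table1_report()`** —
  the steady-state calculus combining intensity and decay fold changes
  into synthesis-rate ratios, termination fractions and
  transcription-rate changes.
* **`scan_cleavage_sites()`, `find_u_tracts()`,
  `cluster_end_positions()`** — an RNase E cleavage-site scanner (+2U and
  −3/4A rules, the "AU clamp"), U-tract detection, and clustering of
  mapped RNA 3'-end positions.
* **`run_pipeline()`** — the staged pipeline
  (simulate → quantify → fit → model → scan → cluster) with CSV/TSV/BED
  artifacts and JSON provenance sidecars; a thin CLI wrapper lives in
  `inst/scripts/chaseterm-cli.R`.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe.

## Worked example

Simulate a chase experiment at the control condition (termination
fraction 0.959, UTR/ORF half-lives 3.1/7.2 min, 2 regions × 3 biological
× 3 technical replicates, σ_Ct = 0.15 cycles), quantify and fit:

```r
library(chaseterm)
library(dplyr)

ct   <- simulate_chase(study_params("mock", seed = 7), condition = "mock")
rq   <- delta_delta_ct(ct)
fits <- fit_decay(rq, n_boot = 1000, seed = 7)
select(fits, -fit)
#> # A tibble: 2 × 10
#>   condition compartment lambda half_life ci_low ci_high     rss n_points
#>   <chr>     <chr>        <dbl>     <dbl>  <dbl>   <dbl>   <dbl>    <int>
#> 1 mock      ORF         0.0961      7.21   6.62    7.77 0.0212        24
#> 2 mock      UTR         0.232       2.98   2.93    3.04 0.00129       24
```

The fitted half-lives (2.98 and 7.21 min) recover the generative truths
(3.1 and 7.2 min); `ci_low`/`ci_high` are 95% bootstrap intervals over
the six replicate series.

Combine published fold changes and half-lives into the synthesis-rate /
termination summary:

```r
rep <- table1_report(
  fc_int_mock = 11, fc_decay_mock = 2.2,
  fc_int_uv = 6.5, t12_uv_utr = 17.1, t12_uv_orf = 7.5,
  fc_int_utr_uvmock = 2.52, t12_mock_utr = 3.1
)
format_table1(rep)
#>                quantity mock UTR/ORF UV UTR/ORF UTR UV/mock
#> 1       FC of intensity         11.0        6.5         2.5
#> 2  FC of decay constant          2.2       0.44        0.18
#> 3  FC of synthesis rate         24.2        2.9        0.46
#> 4 Termination after UTR        95.9%      64.9%          NA
```

Reading the table: under the control condition the 5' UTR is synthesized
24.2× more often than the ORF, so 95.9% of initiating polymerases
terminate within the UTR and only 4.1% read through; under stress the
synthesis ratio drops to 2.9 (64.9% termination), and the UTR's own
synthesis rate falls to 0.46× — a ~2.2-fold transcription-rate reduction
(`rep$transcription_rate_factor[3]`).

Scan an RNA for the RNase E cleavage signature and cluster mapped 3'
ends:

```r
scan_cleavage_sites("GGAAGGGUGGACGUACC")
#> # A tibble: 6 × 6
#>   id     bond plus2_u minus34_a both  n_rules
#> 1 seq1      6 TRUE    TRUE      TRUE        2
#> ...

cluster_end_positions(c(78, 82, 85, 90, 214, 221, 229))
#> # A tibble: 2 × 3
#>   start   end count
#> 1    78    90     4
#> 2   214   229     3
```

Bond 6 carries both rules (uridine at +2, adenine at −3/−4): a candidate
scissile bond. The seven end positions resolve into the two clusters
spanning 78–90 and 214–229 nt downstream of the TSS.

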