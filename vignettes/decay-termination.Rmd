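---
title: "Inferring RNA decay and premature termination from rifampicin-chase qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring RNA decay and premature termination from rifampicin-chase qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaseterm)
library(dplyr)
```

## The model

Many bacterial genes carry long 5' untranslated regions (UTRs) in which a
large fraction of RNA polymerases terminates before ever reaching the
coding sequence. The gene encoding RNase E in cyanobacteria is the
motivating case: its 5' UTR is several hundred nucleotides long, is cleaved
by RNase E itself within a uridine-rich element, and accumulates as an
abundant separate transcript while the full-length mRNA stays rare. The
package quantifies that behaviour from two standard measurements — a
rifampicin-chase decay experiment and steady-state transcript intensities —
under a deliberately minimal steady-state model.

For a transcript segment synthesized at rate $\alpha$ (initiations per
minute) and degraded with first-order decay constant $\lambda$ (min$^{-1}$),
the steady-state level is

$$Int = \frac{\alpha}{\lambda}.$$

With a single promoter and a termination fraction $f$ inside the 5' UTR,
every initiation synthesizes the UTR segment but only the read-through
fraction $1-f$ synthesizes the ORF segment:

$$Int_{UTR} = \frac{\alpha}{\lambda_{UTR}}, \qquad
  Int_{ORF} = \frac{(1-f)\,\alpha}{\lambda_{ORF}}.$$

Taking the ratio of two segments (or of one segment across two conditions)
cancels $\alpha$ only partially, which is the point: the ratio of synthesis
rates is recoverable as

$$FC_{synt} = \frac{\alpha_i}{\alpha_j}
            = \frac{Int_i}{Int_j}\times\frac{\lambda_i}{\lambda_j},$$

the product of an intensity fold change (measurable on an array or by
qPCR) and a decay-constant fold change (measurable by a chase experiment).
For the UTR/ORF comparison under one condition, $FC_{synt} = 1/(1-f)$, so

$$f = 1 - \frac{1}{FC_{synt}},$$

defined when $FC_{synt} \ge 1$; a ratio below 1 carries no evidence of
termination and `termination_fraction()` returns 0 with a flag. For the
UTR compared between a stress and a control condition, $FC_{synt} =
\alpha_{stress}/\alpha_{control}$ reads instead as a transcription-rate
change; `table1_report()` reports its reciprocal as the reduction factor.

## From Ct values to decay constants

**Quantification.** `delta_delta_ct()` implements classic
$\Delta\Delta C_t$ relative quantification with amplification efficiency
fixed at exactly 2: technical replicates are averaged on the Ct scale
(geometric averaging of abundances), $\Delta C_t$ is taken against a
stable reference gene (16S rRNA) matched on condition, biological
replicate and timepoint, and each series is calibrated to its own $t=0$
measurement, so $rq(0)=1$ per series by construction. Biological
replicates are not averaged: each (region × biological replicate) series
passes through to the fit, because averaging before a nonlinear fit
discards the information needed for resampling-based uncertainty.

**Fitting.** `fit_exponential_decay()` minimizes
$\sum (rq - N_0 e^{-\lambda t})^2$ over $\lambda>0,\ N_0>0$ on all points
of a compartment pooled (two probed regions × three biological
replicates). Choices that matter:

* *$N_0$ is free*, not pinned to 1, although normalization forces
  $rq(0)=1$ per series: the calibrator measurement is itself noisy, and a
  free intercept prevents that noise from biasing $\lambda$.
* *Unweighted least squares on the $rq$ scale.* Ct-scale noise is
  multiplicative on abundance, so a log-scale fit would be the exact MLE;
  the $rq$-scale fit is kept because it is the field's standard reading of
  "fit to an exponential decay function", and at the noise levels relevant
  here (0.1–0.2 cycles) the two estimators differ by far less than the
  sampling variability.
* *Numerics.* Starting values come from OLS of $\log rq$ on $t$; the
  bounded "port" algorithm of `stats::nls()` (iteration cap 500) is
  followed by an analytic Newton refinement of the profiled optimum
  ($N_0$ eliminated in closed form), which makes the reported optimum
  reproducible to machine precision — the scale-equivariance guarantee
  ($rq \mapsto c\,rq$ leaves $\hat\lambda$ unchanged to $10^{-9}$) relies
  on this. An L-BFGS-B refinement is the fallback if `nls` fails.
* *Degenerate input.* A course with a non-decreasing trend has its
  least-squares optimum on the $\lambda = 0$ boundary; the fit is flagged
  and the half-life reported as the `Inf` sentinel rather than a
  misleading large number.

**Uncertainty.** `bootstrap_ci()` resamples whole series (the
biological-replicate level — the experiment's natural exchangeable unit)
with replacement, refits, and reports the percentile 2.5/97.5 interval of
the half-life, 1000 resamples by default. A known limitation, measured
rather than hidden: resampling only 6 clusters underestimates the sampling
spread, so the nominal 95% interval covers the truth in roughly 80% of
replications at the default design (the test suite recomputes this
coverage over 100 seeded replications at half-life 3.1 min). Pairs
(point-level), time-stratified and basic/pivotal variants do not do
better; users needing calibrated coverage should increase the number of
biological replicates rather than trust the nominal level at $n=6$
series.

## What the simulator emulates — and what it does not

`simulate_chase()` generates the inputs the pipeline consumes under the
promoter → termination → decay model above, with defaults fixed to the
study conditions rather than tuned afterwards:

| parameter | default | meaning |
|---|---|---|
| `timepoints` | 0, 5, 10, 30 min | chase sampling times |
| `n_regions` | 2 | probed amplicons per compartment |
| `n_bio_reps`, `n_tech_reps` | 3, 3 | replication design |
| `ct_noise_sd` | 0.15 cycles | additive Gaussian Ct noise per well |
| `f_term` | 0.959 (mock), 0.653 (UV preset) | termination fraction |
| half-lives | 3.1/7.2 min (mock), 17.1/7.5 min (UV preset) | UTR/ORF |
| UV `alpha` | 1/2.2 of mock | reduced initiation under stress |

Noise is additive Gaussian on the Ct scale (equivalently log-normal on
abundance), which matches the error structure of real-time PCR; 0.15
cycles is a typical well-to-well SD for technical triplicates. The source
experiments do not report their qPCR noise magnitude, so this default is
a field-realistic choice, not a measured fact. The reference gene is
simulated decay-free ($\lambda_{ref}=0$): rRNA is stable on a 30-minute
timescale. One top-level seed drives every stream; substream seeds are
derived deterministically, so identical parameters give byte-identical
outputs.

Features of real data the simulator does **not** emulate: rifampicin
penetration lag (no delay term — fits to real data with a visible shoulder
should drop early points or extend the model), multi-exponential decay of
processing intermediates, probe-level microarray effects, and any
UV photochemistry of the molecules themselves. Passing recovery tests on
simulated data therefore validates the estimation chain, not those aspects
of an experiment.

**Information limits worth knowing.** With the default design the
recovered termination fraction is pinned very tightly when $f = 0.959$
(the suite's 60-replicate sweep finds essentially every run within 0.02
of truth) but is substantially noisier when $f = 0.653$: the UV half-life
of 17.1 min is long relative to the 30-minute chase window, and $1-f$
amplifies the relative error of $FC_{synt}$, so individual runs scatter
by roughly ±2 percentage points while the estimator stays unbiased (the
suite asserts the median across replicates, not each run). This is an
information limit of the published design, not of the estimator.

## Cleavage-site scanning

`scan_cleavage_sites()` applies the RNase E single-strand cleavage
signature: uridine 2 nt downstream of the scissile bond (+2U rule) and
adenine 3–4 nt upstream (−3/4A rule), together the "AU clamp".
Coordinates use a convention stated everywhere it matters because the
literature's is ambiguous (fragment-end based counts differ by one): a
bond $b$ is the phosphodiester bond between residues $b$ and $b+1$
(1-based, TSS = position 1); "+2" is residue $b+2$; "−3"/"−4" are
residues $b-2$/$b-3$. Scanning is single-strand only (RNA), with no
reverse-complement pass and no secondary-structure filtering — structure
prediction is a separate tool's job and sites inside stable stems will be
false positives of a sequence-only scan.

`find_u_tracts()` reports maximal runs of ≥ 6 uridines by default — the
length of the uridine stretch cleaved in the motivating 5' UTR.
`cluster_end_positions()` groups mapped RNA 3'-end positions by greedy
single-linkage with a 10-nt gap threshold; 10 nt was chosen so that end
positions spread within each of the two empirically mapped regions
(78–90 and 214–229 nt downstream of the TSS, internal gaps ≤ 10 nt for
any plausible draw) stay single clusters while the 124-nt gap between the
regions always separates them. Ties and duplicates are kept (counts
include multiplicity); clustering is order-invariant.

## Reporting conventions

All arithmetic runs on unrounded values; rounding happens once, at report
emission, to avoid artifacts such as $6.5 \times 0.4 = 2.6$ where the
unrounded product is 2.85 → "2.9". Fold changes ≥ 1 are printed to one
decimal, fold changes < 1 to two decimals, percentages to one decimal,
ties rounded half away from zero (`round_half_up()`). A residual gap
documented rather than patched: reconstructing the stress-condition
termination percentage from *printed* (already rounded) inputs gives
64.9%, while the source computation from unrounded fit values printed
65.3%; the difference (0.4 pp) is the information lost to rounding, and
the package reproduces the printed value only where rounded inputs
suffice.

## Problem sizes used in the test suite

The suite validates the estimation chain at the study design throughout.
Sizes were fixed once for a single-CPU run: the bootstrap-coverage check
uses 100 outer replications with 400 resamples each (the analysis default
stays at 1000 resamples); termination-recovery sweeps use 40–60 seeded
replications per condition; oracle-equivalence checks run the scanner
against exhaustive brute force on 1000 random 100-nt sequences and the
NLS against a 2000 × 2000 profiled grid search on 20 random instances.

## Limitations

* Single-promoter assumption: a second promoter inside the UTR would be
  read as (negative) termination; the model cannot distinguish them.
* Single-exponential decay only; no lag or biphasic models.
* The ΔΔCt efficiency is fixed at exactly 2; no dilution-series
  efficiency correction is implemented.
* Bootstrap intervals undercover at the published replication level (see
  above); they are honest summaries of between-series spread, not
  calibrated 95% intervals at $n = 6$.
* The site scanner is sequence-only; it neither learns motifs nor uses
  structure or cleavage-depth data.
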