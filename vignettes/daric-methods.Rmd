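---
title: "Quantifying differential chromatin compartmentalization with daric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential chromatin compartmentalization with daric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daric)
```

## The model

A/B compartments divide chromosomes into megabase-scale active and
repressive territories; the usual PC1-sign call is binary and
scale-incompatible between experiments. `daric` works instead with the
**Preferential Interaction Score**: for bin $b$ on a chromosome with
compartment calls $A$ and $B$,

$$
\mathrm{PIS}(b) \;=\; \log_2
\frac{\overline{oe}(b, A \setminus \{b\})}{\overline{oe}(b, B \setminus \{b\})},
$$

the log-ratio of the bin's average observed/expected contact with
A-labelled versus B-labelled bins of the same chromosome. Because the
obs/exp matrix already divides out the distance decay, PIS is invariant to
the overall contact scale (a global rescaling of the matrix cancels in the
ratio), antisymmetric under swapping the A/B labels, and has a direct
physical reading: positive values mean preferential contact with the
active compartment, and magnitude measures how strongly the bin is
compartmentalized. Trans-chromosomal contacts are not used.

Differential analysis between two conditions then proceeds in four steps:

1. **Smoothing.** Each PIS track is convolved per chromosome with a
   Gaussian kernel (sd `sigma` bins) to suppress bin-level technical
   noise.
2. **Normalization.** For a reference track and another sample, each bin
   contributes $M = \mathrm{PIS}_{ref} - \mathrm{PIS}_{other}$ and
   $A = (\mathrm{PIS}_{ref} + \mathrm{PIS}_{other})/2$. Under the
   assumption that most of the genome is unchanged, any systematic trend
   of $M$ against $A$ over background bins reflects technical
   offset/scale differences (enzyme choice, sequencing depth, cell-cycle
   composition) and is removed: a robust line $M \approx a + bA$ is
   fitted on background bins and subtracted everywhere, and the
   normalized non-reference track is
   $\mathrm{PIS}_{ref} - M_{\mathrm{norm}}$. The reference is never
   modified.
3. **Segmentation.** The residual
   $\Delta\mathrm{PIS} = \overline{\mathrm{PIS}}_{cond1} -
   \overline{\mathrm{PIS}}_{cond2}$ (replicate means, after
   normalization) is segmented by a hidden Markov model with
   one-dimensional Gaussian emissions into $K = 4$ states, relabelled in
   ascending emission mean as `Strong-`, `Weak-`, `Weak+`, `Strong+` so
   they correspond to the four classes of conventional switching
   analysis. Several comparisons (e.g. consecutive time points) can be
   segmented under one jointly trained model so that state definitions
   are shared.
4. **Significance.** With two replicates per condition, the within-
   condition differences $d_1, d_2$ yield at every jointly defined bin
   the four values $\tfrac12(\pm d_1 \pm d_2)$; concatenated over the $N$
   bins they form a null vector of length $4N$ whose mean is exactly zero
   by construction. A Gaussian with mean pinned at 0 (sd = RMS) is fitted
   to it; each bin's one-sided p-value in the direction of its observed
   sign is $P(X > |\Delta\mathrm{PIS}|)$, floored at $10^{-20}$, and the
   significance score is $-\log_{10} p$ (hence capped at 20). `Strong±`
   domains whose mean bin score strictly exceeds 2 are reported as
   significant.

The variability mode summarizes a panel of $\ge 2$ tracks (all normalized
to one reference) by the per-bin mean and population SD of PIS and
segments the 2-D feature into five states with diagonal-Gaussian
emissions; the state with the largest SD emission is `variable`, the two
lowest-SD states are `conA`/`conB` (by mean), the remaining two
`varA`/`varB`. Feature enrichment per state uses the observed/expected
formula $E_i = N_{subset} \cdot N_{universe \in i} / N_{universe}$ with
midpoint assignment.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_size` | 50000 | bp | the standard compartment-analysis resolution; coarser (100 kb) works identically |
| `sigma` | 1 | bins | one-bin Gaussian smoothing removes single-bin noise without blurring domain edges; 0 disables |
| `bg` (`low`, `high`) | 15, 85 | percentiles of residual M | central 70% of bins assumed unchanged; robust to ~15% genuine change per tail |
| `k` | 4 | states | matches stable-A, stable-B, and the two switching classes; larger `k` refines but the strong states stay stable |
| `threshold` | 2 | score units | mean per-bin p of 0.01 within a candidate domain |
| `min_bins` | 1 | bins | no minimum domain size imposed; raise to absorb micro-domains |
| `mean_over` | `"all"` | — | absent sparse pairs count as zero contact; `"nonzero"` averages stored pairs only |
| `tau` (generator) | 0.1 | PIS units | replicate-to-replicate noise of smoothed PIS tracks in well-sequenced experiments |

PIS conventions: the input PC1 must already be oriented A = positive
(`flip =` re-orients individual chromosomes); bins with PC1 exactly 0 are
treated as missing rather than arbitrarily assigned; the self-pair is
excluded from both averages since the diagonal obs/exp is an outlier;
assembly-gap bins are excluded from every score and never appear inside a
reported domain.

## Numerical choices

**Robust regression.** The background line is fitted by IRLS with Tukey's
bisquare loss (`MASS::rlm`, 50 iterations, accuracy `1e-8`). When the
background relation is exactly linear the IRLS scale estimate collapses
to zero, so an ordinary least-squares fit whose maximal residual is below
`1e-10` relative to the response spread is accepted directly; a constant
background M yields the median as intercept with slope 0, and a constant
A (degenerate geometry) yields an intercept-only fit with a warning.

**Iterated background selection.** The background window is defined on
residual M percentiles and re-evaluated: the first pass selects on raw M,
then two further passes reselect bins whose residual from the current
line is central, and refit. One-shot selection on raw M truncates the
response variable and attenuates the fitted slope whenever a real scale
distortion is present; reselecting on residuals removes that bias while
keeping the same definition of background ("bins whose residual PIS is
typical"). `iterations = 1` reproduces the one-shot behaviour.

**HMM fitting.** Baum–Welch with per-step scaling; sequences are split at
missing bins, so no transition is learned or decoded across a gap.
Initialization is deterministic: emission means start at the
$(2m-1)/2K$ quantiles of the pooled observations, refined by k-means
(archetype-seeded, plus a 25-start search under a fixed internal RNG seed
whose state is restored afterwards — the default fit is a pure function
of the data); transitions start at 0.9 self-loop; convergence when the
log-likelihood gain falls below `1e-6` relative, capped at 100
iterations. Emission SDs are floored at $10^{-3}$ of the data SD to
prevent variance collapse. Optional seeded random restarts
(`restarts > 0`) keep the best likelihood. After fitting, states are
sorted by emission mean with ties broken by smaller SD; an exact tie in
both is reported as a degenerate-input error. Runs shorter than
`min_bins` are absorbed into the flanking state with the closer emission
mean, iterating to stability. The 2-D variability HMM standardizes both
features before fitting (they live on different scales) and reports
emissions back on the original scale.

**Significance.** p-values come from the fitted Gaussian rather than the
empirical CDF of the null vector, because the empirical CDF cannot
resolve beyond $1/(4N)$ while the score cap requires $10^{-20}$; an
`empirical` mode is provided for diagnostics. No multiple-testing
correction is applied — domains are thresholded on raw mean scores.

## What the synthetic generator emulates — and what it does not

`simulate_contact_matrix()` builds the checkerboard obs/exp structure:
within-compartment contacts at level `w`, cross-compartment at `c`
(`w > c > 0`, defaults 1.5/0.5 giving PIS = ±log2 3 in the noiseless
case), alternating A/B runs with geometric lengths (mean 15 bins ≈ 750 kb
domains), per-bin compartmentalization-strength multipliers that enrich
same-type and deplete cross-type contacts, and multiplicative lognormal
noise. `simulate_two_cell_experiment()` plants differential domains
directly at the PIS level and distorts the second condition by
`beta * PIS + alpha`, emulating enzyme/protocol scale differences;
replicates add independent Gaussian noise `tau`.

The generator does **not** emulate: distance-dependent contact decay of
raw matrices (it works on the obs/exp scale directly), translocations or
copy-number effects, sub-compartment fine structure, spatially varying
noise (e.g. low-mappability regions beyond hard gaps), or
replicate-specific nonlinear biases. Tests passing on these synthetics
therefore validate the estimators and the inference logic, not robustness
to every artefact of real Hi-C; on real data the normalization and gap
masks carry that burden.

Test and acceptance problem sizes are deliberately desk-scale: 400-bin
chromosomes (20 Mb at 50 kb) for pipeline simulations, up to 200 bins for
dense-oracle comparisons, 50 replicate simulations for calibration — the
method is linear-algebraic per chromosome and scales to full genomes
unchanged.

## Known limitations

* **Short spurious domains under a true null.** The per-bin test is
  calibrated (a ~2% tail at score 2 by construction), and smoothing
  correlates neighbouring bins, so among hundreds of bins a genuinely
  unchanged comparison still yields of order one short (3–6 bin) extreme-
  state excursion whose mean score exceeds 2. Without multiple-testing
  control this is irreducible; users comparing truly similar samples
  should treat isolated sub-5-bin significant domains with caution or
  raise `min_bins`. The acceptance script measures both sides of this
  trade-off (`null_p01_fraction_pct`, `null_zero_domain_runs_pct`).
* **2+2 replicate design.** The null construction is defined for exactly
  two replicates per condition; other designs run without significance.
* **PC1 orientation is the caller's responsibility.** The package does
  not consult gene density; feed correctly oriented PC1 (A = positive)
  and use `flip` per chromosome when needed. An all-one-sign chromosome
  triggers a warning.
* **Edge renormalization.** Smoothing renormalizes the truncated kernel
  at chromosome ends and next to gaps, which preserves constants but
  means edge bins average over fewer neighbours; interior mass is
  preserved to numerical precision.
* The five variability labels formalize a qualitative description; on
  panels with little genuine variability the `variable` state is defined
  only up to the noise floor, and an exactly constant SD feature is
  rejected as degenerate rather than segmented.

## A minimal run

```{r example, eval = FALSE}
cfg <- simulation_config(n_bins = 400, tau = 0.1, alpha = 0.2, beta = 0.9,
                         seed = 29)
exp2 <- simulate_two_cell_experiment(
  cfg, planted = tibble::tibble(from_bin = 100, to_bin = 129, delta = 1))
res <- daric_compare(exp2$cell1, exp2$cell2, seed = 0)
tidy(res$hmm)        # emission table: Strong+ mean ~ +0.95
res$significant      # the planted 1.5 Mb window, mean score at the cap
autoplot(res$hmm)
```
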