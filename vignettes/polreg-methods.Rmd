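---
title: "Predicting regulatory TFs from PolII promoter binding: methods and design"
author: "polreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting regulatory TFs from PolII promoter binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polreg)
```

# The problem

RNA polymerase II (PolII) occupancy at a gene's promoter tracks transcription
more directly than steady-state mRNA does, because mRNA levels fold in
post-transcriptional effects. Given paired PolII ChIP-seq samples — a control
and a treatment condition, binned into fixed-width genomic windows — the
question this package addresses is: *which transcription factors (TFs) drive
the observed changes in promoter-level PolII binding?* The answer is built in
five stages, each usable on its own:

1. **Normalization** of the paired binned track (MA-plot LOWESS);
2. **Differential binding** calls on promoter windows (the pi-value);
3. **Motif scanning** of promoter sequences into a thresholded binding
   matrix `R`;
4. **Two-step TF prediction**: an ensemble of random-subset regressions that
   assigns each motif a regulatory capacity (RC), followed by backward
   stepwise finalization, run over a grid of TSS sub-intervals;
5. **Network inference** over the predicted TFs via a significant
   interaction score (SIS) on promoter co-binding.

A synthetic-data generator produces complete, ground-truthed input bundles,
so every stage is testable end to end without any external download.

# Normalization

For bin $i$ with control count $x_{i1}$ and treatment count $x_{i2}$,

$$M_i = \log_2\frac{x_{i1}}{x_{i2}}, \qquad
  A_i = \log_2\sqrt{x_{i1}\,x_{i2}}.$$

A LOWESS curve $\hat M(A)$ (tricube local linear regression, three
robustifying iterations, span 0.3 by default, fitted per chromosome) captures
the systematic intensity-dependent trend; the corrected values are
$M'_i = M_i - \hat M(A_i)$ and the adjusted quantities

$$x'_{i1} = 2^{A_i + M'_i/2}, \qquad x'_{i2} = 2^{A_i - M'_i/2},$$

which preserve each bin's geometric mean exactly (a property the tests
assert to $10^{-9}$). Per-read weights $r' = x'/n$ are emitted for bins with
reads; when no separate read track is supplied, $n$ is the sample's own
count, making $r'$ a pure scaling weight used by the promoter quantifier. A
total-mapped-reads (TMR) scaler is included as the global baseline the LOWESS
method improves upon.

Numerical choices: bins with both counts zero are excluded from the fit and
carry $M = 0$; when exactly one count is zero a pseudocount of 0.5 is added
to both (the log is otherwise undefined). With fewer than 30 fit-eligible
bins the normalizer refuses to fit and falls back to the identity with a
warning.

**What an M-vs-A fit can and cannot remove.** The fit conditions on $A$, so
it removes bias only insofar as bias is recoverable from $A$. Two
consequences shape the tests. First, under overdispersed counts the per-bin
residual $|M'|$ is dominated by counting noise (a negative binomial with
gamma dispersion 0.2 leaves ~0.7 log2 units of irreducible per-bin scatter,
at any depth), so the normalization-efficacy diagnostic uses noise-free
expectation counts (`count_noise = "none"`), where the residual measures the
smoother alone. Second, the method's standing assumption — changed bins must
be a local minority at every $A$ — fails if changed bins form their own
isolated cluster on the $A$ axis; the generator therefore models
heterogeneous genomic coverage (below), which is also what real data look
like.

# Differential binding: the pi-value

Promoter windows are TSS-relative, strand-oriented, 0-based half-open;
quantities are pro-rata sums of adjusted bin values over the window. With
$p^{(k)}_i = \log_2(q^{(k)}_i + 1)$ the log promoter quantity in condition
$k$, the log-fold-change magnitude is $\varphi_i = |p^{(1)}_i - p^{(2)}_i|$
and

$$\pi_i = \varphi_i \cdot (-\log_{10} P_i),$$

where $P_i$ is a two-sided Fisher exact p-value on the gene's raw window
reads against the remaining library reads, per condition. The Fisher test is
computed on raw (integer) reads because exact tests require counts; the fold
change uses normalized quantities. The test itself is a direct
hypergeometric enumeration over the table support with the conventional
$1 + 10^{-7}$ relative tie tolerance.

Genes with $\pi$ above $\mathrm{mean}(\pi) + k\,\mathrm{SD}(\pi)$, $k = 3$ by
default, are called differential. The threshold is phrased "mean plus three
times the dispersion"; we read dispersion as the standard deviation —
variance has squared units, and an SD-based rule is invariant under
rescaling of $\varphi$ — but `dispersion = "variance"` preserves the literal
reading. Binding-mode calls use the relative change
$(q_2 - q_1)/\tfrac{q_1+q_2}{2}$ with a $\pm 2.5\%$ constant band; boundary
values are "constant".

# Motif scanning and the binding matrix

PWM counts (TRANSFAC or JASPAR dialects) gain a 0.01 pseudocount per cell,
are column-normalized to frequencies, and scored as log2-odds against a
uniform background (a raw log-probability mode exists; because sites are
selected by *rank*, the two modes select identical sites). Every promoter is
scanned on both strands; windows containing N are dropped.

Per motif, the site-score threshold is the 2,000th-highest pooled score
across the corpus — or, for small synthetic corpora, the equivalent fraction
of the gene count (2,000 of 34,055 promoters ≈ 5.9%). All sites scoring at
least the threshold pass, so ties can admit more than the nominal rank; that
tie rule is what makes planted consensus instances (which all share the
motif's maximum score) pass deterministically. `R[i, j]` is the best passing
score of motif `j` in promoter `i`, else 0. Sub-interval matrices are formed
by *masking* sites whose extent leaves the sub-window, never by rescanning,
so thresholds stay fixed across the interval grid.

# Two-step TF prediction

Per interval, the response is $P_g = \log_2\frac{S^t_g + 1}{S^c_g + 1}$ over
genes whose combined raw window reads reach 5; the +1 guards empty windows
and is negligible at the depths the filter admits.

**Step 1 (RC scoring).** Each of `n_iter` iterations draws $k = 5$ motif
columns uniformly, fits OLS of $P$ on those columns plus an intercept, takes
the residual sum of squares $E$, and adds $1/\max(E, 10^{-12})^{\alpha}$
(with $\alpha = 5$) to each drawn motif's RC. The $10^{-12}$ guard bounds
the contribution of exact fits, which the unguarded formula would make
infinite. Subsets are drawn with repeats allowed (pure uniform sampling).
The implementation precomputes the Gram matrix $X^\top X$ and $X^\top P$
once, reducing each subset to a $(k+1)\times(k+1)$ solve; exactly collinear
subsets fall back to a tiny ridge rather than aborting. An exhaustive mode
evaluates every subset once and is the reference the sampled mode is tested
against. The top 10% of motifs by RC (ties broken by motif id) become
candidates.

**Step 2 (stepwise finalization).** Backward elimination from the full
candidate model: while any coefficient's t-test p-value exceeds 0.01, the
worst variable is removed and the model refit. The removal criterion equals
the final significance level, so every retained coefficient satisfies
$p \le 0.01$; exactly collinear candidates are reduced up front (the later
motif id loses). Retaining nothing is allowed.

The grid spans all 12 windows from (−400, +200) to (−600, +500) in 100 bp
steps per end; per-interval finalized sets are merged by union, and the
motif × interval coefficient matrix supports comparing a TF's motifs across
intervals (with a per-TF sign-consistency flag). `run_two_step()` takes an
explicit gene universe: the orchestrator passes the differential set when it
is large enough to support the regressions and falls back to all
read-filtered genes otherwise — on small corpora a mean + 3 SD cut can
select too few genes to fit 10% of the motif panel.

# The SIS network

Among the differential-gene promoters, TF $i$ binds gene $g$ if any of its
motifs has $R_{gj} > 0$. With $\mathrm{Int}_{ij}$ the number of co-bound
genes and $\mathrm{Int}_{i\cdot} = \sum_{j \ne i}\mathrm{Int}_{ij}$,

$$\mathrm{SIS}_{ij} = (-\log_{10} P_{ij})\left(
  \frac{\mathrm{Int}_{ij}}{\mathrm{Int}_{i\cdot}} +
  \frac{\mathrm{Int}_{ij}}{\mathrm{Int}_{j\cdot}}\right),$$

with $P_{ij}$ the Fisher exact p-value of the 2×2 co-binding table over the
gene universe. Log base 10 matches the pi-value; pairs with an undefined
margin score 0 and never form edges. Edges at or above
$\mathrm{mean} + k\,\mathrm{SD}$ (default $k = 1$; the variance reading is
switchable, as for pi) form the network; hubs are reported by degree.

# The synthetic-data generator

`simulate_genome()` emulates the statistical structure the pipeline assumes,
with ground truth recorded for every choice it makes:

* **PWMs**: random matrices of width 6–12 with an 0.85-frequency dominant
  base per column. Causal motifs draw widths 9–12 so that a planted
  consensus is effectively unique in a ~1 Mbp promoter corpus (at width 8,
  ~30 chance consensus windows would rival the ~75 planted ones and dilute
  the planted indicator). About 10% of TFs own two motifs.
* **Promoters**: 1,100 bp windows (−600..+500 around each TSS), uniform
  random sequence, with causal-motif consensus instances planted at uniform
  offsets and random strands in responsive genes (30% of genes; each causal
  motif planted with probability 0.5 per responsive gene).
* **Counts**: negative-binomial background, mean 20 per 1 kb bin, gamma
  dispersion 0.2 — deliberately overdispersed so the normalizer is exercised
  beyond Poisson noise. Promoter windows are 5-fold enriched in both
  samples (PolII concentrates at promoters). A per-bin depth offset with SD
  1 log2 unit, shared by both samples, models heterogeneous genomic
  coverage; it cancels from every log-ratio while spreading bins along the
  $A$ axis — without it, the enriched promoter bins form an isolated $A$
  cluster in which changed bins locally dominate and the robust LOWESS fit
  absorbs the planted biology (we observed planted effects of 1.6–2.0 log2
  units shrink to 0.1–0.4 under a flat background).
* **Treatment**: the control expectation scaled over gene $i$'s promoter
  bins by $2^{\sum_j \tilde R_{ij}\beta_j + \mathcal N(0, \sigma)}$
  (defaults: $|\beta| \in [1, 2]$ with random signs, $\sigma = 0.25$) and
  genome-wide by the smooth depth bias
  $\log_2 b(t) = 1 + t - 2.5\,t^2$ in scaled position $t$, whose mean
  absolute log2 value (~0.67) is large enough that raw and corrected M are
  clearly separated in the diagnostics.
* `count_noise = "none"` replaces sampled counts by rounded expectations,
  used by normalization diagnostics where sampling scatter would mask what
  is being measured.

What the generator does **not** model: read-level artifacts (mappability,
GC content, duplicates), chromatin state, motif competition or cooperative
binding, correlated occupancy between neighboring genes, and realistic motif
information-content profiles. Passing tests therefore demonstrate that the
statistical machinery recovers the planted linear structure under
overdispersed counts and a smooth bias — not that the model assumptions hold
in any particular real dataset.

# Study sizes used by the automated checks

The test suite and `scripts/acceptance.R` run the full pipeline on bundles
of 500 genes × 60 motifs (5 causal) with the ensemble in its fast mode
(100,000 iterations), 20 replicate seeds for the recovery and null studies,
and ~5,000-bin tracks for the normalization diagnostics. These sizes keep a
complete run in the minutes range on one CPU while leaving each check
well-powered; all of them scale up through function arguments
(`n_iter = 1e6` is the default for real-size panels of several hundred
motifs).

# Known limitations

* Position-dependent bias is removed only to the extent it is expressible
  as a function of $A$; the vignette section on normalization explains why
  this is intrinsic to MA-plot methods, not an implementation limit.
* The Fisher table for differential binding (gene window vs remaining
  library) and the co-binding universe for SIS (differential promoters) are
  the standard operationalizations of quantities the method sketch leaves
  open; both are documented at the function level and covered by oracles.
* The rank threshold is calibrated per motif; a global pooled-rank variant
  is not implemented.
* Stepwise selection inherits the usual caveats of significance-driven
  model search, and the two-step design compounds them: RC preselection
  picks the most data-correlated motifs before stepwise tests them on the
  same data, so under a pure-noise response the best-of-panel order
  statistic slips under `p = 0.01` in a sizable fraction of intervals
  (retained null p-values cluster just below the threshold). Per stepwise
  run the mean null retention stays below one motif, which is what
  `alpha_remove` controls; the 12-interval *union* of null retentions is
  about twice that, because the intervals share data while their false
  picks differ. Interpret the merged set accordingly: membership backed by
  a single interval at a borderline p-value is weak evidence.
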