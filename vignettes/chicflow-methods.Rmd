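---
title: "Models and methods behind chicflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chicflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the parameter choices and
the numerical decisions inside `chicflow`, in the order the pipeline runs.
It also states precisely what the bundled simulator does and does not
emulate, so the reader can judge what a passing closed-loop test implies
about real capture Hi-C data.

## Coordinate conventions

All internal coordinates are 0-based and half-open; 1-based formats (BED
is already 0-based; GRanges used internally for overlap arithmetic is
1-based closed) are converted only at the boundary. Bins of width `res`
cover `[k*res, (k+1)*res)`; the last bin of each chromosome is truncated.
A single genome-wide 1-based linear bin index orders bins chromosome by
chromosome.

## Digestion and ditag filtering

`digest_genome()` scans for literal occurrences of the recognition
pattern (overlaps included; IUPAC ambiguity codes never match) and cuts at
`occurrence + cut_offset`. The offset defaults to +1, the position at
which HindIII cleaves its palindromic site A^AGCTT; it is configurable
for other enzymes.

Ditags keep only read pairs with MAPQ strictly above 30 on both ends —
the conventional unique-alignment cut for single-end-mapped Hi-C reads —
then collapse PCR duplicates on the coordinates and strands of both
canonically ordered ends. Experimental background is removed by a
deterministic rule table over read orientation and restriction-site
geometry:

| geometry | orientation | class |
|---|---|---|
| either end > `max_site_distance` from any cut | any | `no_site` |
| same fragment | inward (+/−) | `non_digested` |
| same fragment | outward (−/+) | `self_ligation` |
| adjacent fragments | outward | `circularized` |
| anything else | any | `valid` |

`max_site_distance` defaults to 800 bp: sonication fragments peak near
500 bp, so a genuine ligation-junction read must start within a few
hundred bases of a cut site. The `no_site` rule takes priority because it
is evidence the read cannot derive from a ligation junction at all.
Inward-facing pairs on adjacent fragments are retained as valid: they are
indistinguishable from genuine short-range re-ligation contacts, and
dropping them would bite into real signal. Classification is invariant to
the order of the two ends.

## Bias correction

Per-bin visibility bias (capture efficiency, GC, mapability,
fragment-length structure) is multiplicative to good approximation:
observed counts look like `T_ij * b_i * b_j`. The correction estimates
the per-bin factor from trans contacts, which carry no distance
structure: `w_i` is the number of reads joining bin i to other
chromosomes, `N_i` the number of populated trans entries in row i, and
`W`, `A` their totals. The normalized weight

    what_i = (w_i / N_i) / (W / A)

is a per-populated-entry trans rate relative to the genome average. Each
iteration divides every entry `M_ij` by `what_i * what_j` and recomputes;
the procedure stops when `max |what_i - 1| <= tol` (default 1e-3, cap 100
iterations, non-convergence flagged and never silent). Total matrix mass
is restored after convergence, so the correction only redistributes
counts, and the whole procedure is scale-equivariant.

Two design points deserve emphasis:

* **N counts trans entries only.** If `N_i` also counted cis entries, the
  fixed point would demand per-chromosome trans row-sum totals that are
  mutually inconsistent (each chromosome's cis population enters its own
  target but not its partners'), and the recursion stalls at a nonzero
  floor instead of reaching unity. Restricting `N_i` to the same trans
  entries the weights are built from makes the fixed point attainable;
  empirically the recursion then contracts geometrically to machine
  precision.
* **Exclusion before iteration.** Bins whose initial weight is more than
  three standard deviations below the mean weight, and bins with no trans
  reads at all, cannot reach the unit fixed point and are removed before
  iterating (and marked invalid downstream).

The correction is performed globally rather than in 10 Mb windows: the
update is an entrywise division by per-bin factors, so visiting entries
window by window is algebraically identical and windowing is purely a
memory-footprint device. `window_views()` still provides the 10 Mb
tiling used for heatmap export and the per-interval significance fits.

A caveat that matters at shallow coverage: `w_i / N_i` responds to bias
only through multiply-hit matrix cells. When almost every populated trans
cell holds a single read, `N_i` tracks `w_i` and the estimator goes
blind; deeply covered (capture-enriched) rows are corrected well, sparse
rows only weakly. This is intrinsic to trans-rate weighting, not to the
implementation, and it is why the significance model below does not
assume residual bias is zero.

## Distance normalization

The expected contact frequency f(d) is the mean corrected count per valid
intra-chromosomal bin pair at separation d, smoothed on the log10
distance axis by *local-linear* kernel regression of log f (Gaussian
kernel, bandwidth 0.1 decades, observations weighted by the number of
pair slots at each separation). Local-constant smoothing would flatten
the profile at the boundaries of its support (the one-sided kernel pulls
toward the interior); local-linear fitting is exactly unbiased for a
power law, which is linear in log-log space. Monotone non-increase is
then enforced by isotonic regression, and power-law exponents are fitted
by least squares of log10 f on log10 d over 9 kb–0.5 Mb (short regime)
and 0.5–7 Mb (long regime). Interpolation between grid points is
log-log linear with constant extrapolation outside the support.

Cis entries are divided by f(d) at their bin separation; trans entries
and the diagonal are untouched. An optional coverage attenuation
raises f(d) to the power `gamma(c) = min(1, (c/c_ref)^lambda_cov)` for
pairs whose lower-coverage bin has capture coverage `c` below the
reference `c_ref`; a zero-coverage interactor is then left unnormalized.
This implements the qualitative contract that low coverage should make
distance normalization less penalizing; the specific functional form is
this package's own, it is off by default, and no test depends on it.

## Significance model

Normalized strengths within a fitting group are modelled as a
zero-inflated Weibull: mass π at exactly zero plus a Weibull(κ, λ) tail.
π is the observed zero fraction over the *universe* of eligible pairs
(unobserved pairs are zeros — they count toward both π and the
multiple-testing burden). κ and λ maximize the right-truncated
likelihood over the nonzero values at or below their 95th percentile,
each density renormalized by the Weibull CDF at the truncation point
(truncation without renormalization would bias the shape). The
truncation keeps genuinely interacting pairs from inflating the null
tail. The fit starts from moment-style values (shape from the log-spread,
scale from the mean) and optimizes with BFGS on log-parameters, falling
back to Nelder–Mead; degenerate inputs (all zeros; all nonzero values
identical) return flagged sentinel fits, never silent successes. The
upper-tail probability of a contact of strength x is 1 at x = 0 and
`(1 - π) exp(-(x/λ)^κ)` beyond.

Eligibility: valid bins, at least one capture-enriched bin in the pair
(E–E or E–N), and cis separation strictly above 10 kb (long-range calls
only; at 9 kb bins that means a bin gap of at least two).

Fitting groups follow the interval structure of the data: test-region
(E–E) contacts pool into one fit; E–N contacts fit per (cis/trans,
chromosome, 10 Mb window of the interactor bin). Two refinements were
necessary for honest tail behaviour at realistic coverage:

* **Distance-octave strata for cis fits.** Dividing a count by f(d)
  multiplies its variance by 1/f(d)²-relative factors, so normalized
  strengths at 5 Mb are several times more dispersed than at 0.5 Mb even
  under a perfect null. A single Weibull fitted across that range
  understates the far tail and manufactures false calls. Cis groups are
  therefore stratified by octave of separation (doubling windows above
  the 10 kb floor), restoring within-group homoscedasticity.
* **Randomized-quantile dithering.** At desk-scale depth, trans strengths
  are small integers; a continuous Weibull fitted to values concentrated
  on one or two atoms degenerates to a near-point mass and assigns
  absurdly small tail probabilities to the next integer. Each count is
  spread uniformly over the unit below it (the Dunn–Smyth residual
  construction) before fitting and evaluation, which restores both the
  fit and the uniformity of null P values. The dithering draws from the
  session RNG; seed for exact reproducibility.

Groups with fewer than 200 nonzero observations fall back to coarser
pools (interval → chromosome → kind), each fallback pooling *all*
entries under its prefix; and when even the pooled fit rests on fewer
than 200 observations, no P value may exceed the empirical resolution of
the pool (a floor of `(1-π)/(n+1)`), because tail extrapolation from a
handful of points is meaningless.

q-values are Benjamini–Hochberg step-up over the full eligible universe
(BH is the conservative, parameter-free member of the q-value family).
With several libraries, the intersection rule applies: a contact is
reported as shared only when q < 0.05 in every library. This intersection is what controls false
discoveries in practice — the Weibull's doubly-exponential local tail is
thinner than a Poisson-like count tail, so any single library's marginal
calls include model-mismatch false positives that do not replicate
across independent libraries; the closed-loop tests quantify this.

The three-sample overlap probability (how surprising is it that k
contacts reach significance in all three libraries?) is computed exactly
through a hypergeometric chain — |s₁∩s₂| is Hyper(N₂; n₁, n₂), and given
that overlap m, |s₁∩s₂∩s₃| is Hyper(N₃; m, n₃) — evaluated in log space
so tails far below machine precision are still resolved; the
binomial-on-N₁ approximation (each element of S₁ in all three samples
with probability Π nᵢ/Nᵢ) is available as an option. The exact form is
the one that matches exhaustive enumeration over small universes and
Monte Carlo draws of fixed-size samples.

## Domains

The directionality index of a bin contrasts its upstream contact sum A
with its downstream sum B within 495 kb flanks:
`D = |A - B| * (B - A) / (A + B)`, zero when A + B = 0. Its magnitude is
`(A - B)²/(A + B)`, which for unbiased Binomial(total, 1/2) splitting is
asymptotically χ²₁ — verified by simulation in the tests. Near
chromosome ends the window is truncated *symmetrically* (both flanks
shrink to the shorter side): a one-sided window would make every
chromosome end look structurally directional, while the symmetric
truncation keeps unbiased bins unbiased at the cost of power in the last
window. Bins with no room on one side carry D = 0. The index is computed
on bias-corrected, *not* distance-normalized counts — distance
normalization would whiten exactly the directional signal being sought.

Segmentation uses a 3-state HMM (upstream-biased / none /
downstream-biased) over the variance-stabilized signal
`y = sign(D)·sqrt(|D|)`, which is approximately standard normal for an
unbiased bin. Emissions are Gaussian with a common scale set to the MAD
of the nonzero track (robust to boundary spikes and invariant to global
matrix scaling) and state means at ±6 times that scale — far enough out
that the maximum of thousands of null bins stays in the neutral state.
Transitions are sticky (0.9 self-transition); decoding is Viterbi. Bins
with no signal get neutral emissions so a boundary run can bridge them;
single-bin biased runs are suppressed as noise spikes (genuine boundary
runs persist over the half-window their contrast spans). A domain runs
from the start of a downstream-biased run to the end of the next
upstream-biased run (consecutive same-state runs merge into one
boundary); a chromosome end may stand in for the missing flank of a
domain flush against the edge. Calls shorter than 3 bins are dropped.

## Downstream statistics

* **Enrichment factor**: libraries are first subsampled to equal raw
  ditag counts (PCR duplication grows nonlinearly with library size, so
  size-matching is essential); a ditag is on-target when either end
  falls in a target interval; the factor is the ratio of on-target
  fractions, with a per-9-kb-bin on/off mean-count ratio as a secondary
  view. The uniform seeded subsample stands in for the flow-cell-area
  subsetting used with real sequencers, which is hardware-specific.
* **Association overlap**: two-sided Fisher exact test on the 2×2 table
  of significant × low-association bins. "Low association" means the bin
  holds a SNP within one order of magnitude of its region's smallest
  P value. Two-sided is the conservative default and is validated
  against direct hypergeometric enumeration.
* **Regulatory-element overlap**: the observed proportion of significant
  bins overlapping a regulatory class is compared against random
  same-size bin samples drawn without replacement from the valid-bin
  universe; P = m/N with "< 1/N" reported when no sample reaches the
  observed proportion.
* **TF sharing**: per interaction, the number of factors with a peak in
  both bins; controls permute interactor bins across calls, rejecting
  same-test-region pairings; two-sided Mann–Whitney U compares the two
  count vectors, with a flagged P = 1 in the fully degenerate case.

## The simulator, and what passing tests mean

`simulate_genome()` plants recognition sites at exponential spacing
(mean 3 kb, matching the genome-wide HindIII average) and, on request,
generates sequence from which stray pattern occurrences are scrubbed, so
digestion recovers exactly the planted sites. `simulate_library()` draws:

* cis background with per-pair contact probability proportional to the
  two-regime power law of separation (exponents −0.52 / −0.97,
  breakpoint 0.5 Mb, support to 7 Mb), trans background uniform over
  cross-chromosome pairs;
* log-normal per-bin bias (σ = 0.3), applied symmetrically `b_i b_j` by
  rejection — exactly the multiplicative model the correction assumes,
  making planted-bias recovery a fair test;
* capture enrichment as *additional independent* bait-touching ditags
  (real capture enriches distinct molecules; exact copies would be
  eaten by the duplicate filter), with a multiplicity calibrated so a
  size-matched enrichment measurement returns the configured 130-fold in
  expectation;
* planted loops as excess Poisson mass at anchor bin pairs, fold ×
  the exact expected background of that pair (matching the alternative
  hypothesis of the calling model without baking in its null); planted
  domains as a within-domain rate multiplier;
* artifact ditags with the exact geometry of each background class, and
  PCR duplicates as coordinate-identical copies;
* every non-artifact end within 400 bp of a restriction site, in bins
  containing at least one site — ligation junctions live at restriction
  sites, and siteless bins are precisely the ones the valid-bin filter
  exists to drop.

Defaults are a desk-scale study: two 20 Mb chromosomes, 5×10⁵ ditags,
one 18 kb bait region per chromosome, artifact fractions of a few
percent each, 5% duplicates. Closed-loop tests plant loop anchors at
0.3–2.2 Mb from the bait — the sub-TAD scale at which validated
enhancer–promoter contacts live — and 900 kb domains of 3× internal
contact enrichment.

What the simulator does **not** emulate: sequencing error and alignment
ambiguity (ends are emitted as perfect coordinates with MAPQ 60),
mapability structure (synthetic genomes are uniformly mappable, so the
mapability filter is exercised by unit tests rather than the closed
loop), GC-dependent amplification curves, overdispersion of the
background beyond the planted multiplicative bias (counts are Poisson
conditional on the planted structure), translocations/CNVs, and
cell-to-cell heterogeneity. Passing closed-loop tests therefore
demonstrates that the pipeline inverts its own generative assumptions at
realistic scale — bias recovery, decay recovery, artifact removal, loop
and domain recovery — not that those assumptions exhaust real cHi-C
data. One concrete consequence, visible in the tests: because the
simulated null is Poisson-tailed while the significance model is
Weibull-tailed, single-library call lists contain a small model-mismatch
excess, and the three-library intersection is the calibrated quantity.

## Numerical choices and problem sizes

* Bias-correction tolerance 1e-3 on `max|what - 1|`, max 100 iterations.
* Smoothing bandwidth 0.1 decades; template fit ranges exactly 9 kb,
  0.5 Mb, 7 Mb.
* ZIW truncation quantile 0.95; minimum 200 nonzero observations per
  fitting group; ties in strength receive identical P values (dithering
  randomizes within the unit interval below each count, not between
  tied counts' order statistics in any systematic direction).
* Minimum cis call separation 10 kb (strict); FDR threshold 0.05.
* DIX window 495 kb; HMM self-transition 0.9; state means ±6 MAD;
  minimum domain length 3 bins.
* Test problem sizes were chosen to keep the full suite around a few
  minutes on one core: 10⁶ contacts for exponent recovery, 5×10⁵-ditag
  libraries for the closed loops, 10⁴ Monte Carlo samples where a
  production analysis would use 10⁷ (the "< 1/N" reporting convention
  scales accordingly), 2×10⁴ draws for distributional checks.

## Known limitations

* Trans-rate weights cannot correct bias in rows with almost no
  multiply-hit trans cells (see above); at production depth this is not
  a constraint, at shallow depth residual per-bin bias survives into the
  normalized strengths and widens the fitted null — which is the correct
  behaviour, but costs power.
* E–E (test-region) pairs at desk scale are far too few for a stable
  null fit; the empirical P floor makes them effectively untestable
  rather than unreliably tested. With production-scale capture designs
  (hundreds of enriched bins) the pooled test fit behaves normally.
* The HMM domain caller targets clean two-state directional structure;
  nested or hierarchical domains are out of scope.
* The coverage-attenuation form for distance normalization is a declared
  extension with no reference implementation to compare against; it
  ships off by default.
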