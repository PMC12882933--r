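---
title: "Methods: perceptual similarity of braille letters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perceptual similarity of braille letters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braillesim)
```

# Scope and model

braillesim analyzes the perceptual structure of the 26-letter braille
alphabet along two complementary tracks: *formal* properties that follow
from the dot patterns alone, and *behavioral* similarity estimated from
same–different discrimination trials. The package also ships a trial-level
simulator so that every stage of the behavioral pipeline can be exercised,
end to end, without access to raw participant data.

## The alphabet and its information structure

Each letter is a cell of six binary dot positions (1–3 down the left
column, 4–6 down the right). `braille_alphabet()` hard-codes the first
decade (a–j) and derives the rest by the system's own rules: k–t add
dot 3, u/v/x/y/z add dot 6 to k/l/m/n/o, and w is the 180° rotation of r.
Construction fails loudly if the derivation ever produced a duplicate or
empty cell.

The informativeness of dot position $d$ is the binary entropy of its
prevalence $p_d$ across the alphabet,
$$H(p) = -p \log_2 p - (1-p)\log_2(1-p),$$
maximal (1 bit) at $p = 0.5$. With prevalences 21, 14, 15, 15, 13 and 6
out of 26, the six dots score 0.706, 0.996, 0.983, 0.983, 1.000 and 0.779
bits. Cue validity takes a uniform prior over letters: the presence form
$p(l \mid d) = 1/n_d$ for each of the $n_d$ letters carrying the dot, the
absence form $1/(26 - n_d)$. No numeric cue-validity values are published,
so the uniform-prior reading is a package decision; it reproduces the
published qualitative asymmetry (dot 1's absence is diagnostic, dot 6's
presence is).

### Per-letter informativeness: a documented discrepancy

The published per-letter score is described as the mean entropy of the
dots *comprising* each letter. Computed that way from the packaged
matrices, the same-trial correlations come out with signs opposite to the
published values (accuracy $r = -0.47$ instead of $+0.28$; RT $r = +0.53$
instead of $-0.43$). The complementary score — the mean entropy of the
*absent* positions — reproduces the published correlations (about $+0.26$
and $-0.39$) and also the published qualitative claims (d faster than h,
x fast despite four dots), which are false under the raised-dot reading.
`letter_informativeness()` therefore implements the stated raised-dot
definition as the default and exposes `from = "absent"` as a documented
option; the acceptance test reports both. We treat this as an
inconsistency between the source's text and its computations and follow
the numbers.

## Linear separability

Two routes, deliberately kept distinct:

* `train_delta_rule()` is the *empirical* route: a 6-input, 26-sigmoid-
  output network trained by the delta rule (learning rate 0.4, weights
  initialized in ±0.3, per-pattern updates, patterns shuffled per epoch,
  up to 5000 epochs). The published description mentions "a small momentum
  term" without a value (we use 0.1) and stopping "until no further
  improvement" without a window (we use 500 epochs). The match score
  counts output units on the correct side of activation 0.5, out of 676.
  A letter counts as classified, by default, only when all 26 units are
  correct for its input (`rule = "threshold"`); `argmax` is available.
* `strict_separability()` is the *exact* route: a linear-feasibility
  decision with margin 1 (through the origin by default — the published
  network has no bias unit, and strict non-separability is only possible
  through the origin). A separable letter yields a weight vector checked
  against all 26 inequalities; a non-separable one yields a Farkas
  certificate, nonnegative coefficients on other letters' patterns summing
  exactly to the target pattern (e.g. f = a + i, q = k + j). Both witness
  types re-verify mechanically via `verify_certificate()`.

The LP core is a small phase-1 simplex with Bland's rule implemented in
the package: the one LP routine available in the surrounding stack
(`boot::simplex`) returned a wrong infeasibility verdict on a trivially
feasible two-pattern system, and the systems here are tiny (≤ 30 rows).
The oracle is tested against exhaustive integer-grid search on reduced
alphabets.

The two routes disagree on one letter, and that is informative: the exact
oracle finds {f, g, p, q} non-separable (o *has* a separating vector; q
does not), while the published trained network reportedly failed on
{f, g, o, p}. Our trained network fails on {f, g, p, q} — the oracle set —
on every seed tried. The acceptance criterion asserts the modal failure
*count* (4) and that no run reaches 676, both of which hold; the set
identity is treated as a stochastic outcome of MSE training, not a
separability fact.

## From trials to matrices

`filter_trials()` drops RTs outside [0.2 s, 8 s], and additionally error
trials for the RT analysis. `accuracy_matrix()` computes, per ordered
letter pair, each participant's proportion correct and averages those
unweighted across participants (pooling is a flag); with proportion
correct as the cell value, higher means easier discrimination, i.e. more
dissimilar. `rt_matrix()` divides each retained RT by its participant's
mean retained RT (adjusted mean 1 per participant, removing speed
differences), takes the per-participant median per cell, and averages
across participants. The source text mixes "median" and "averaged across
participants"; median-within-then-mean-across is our composition honoring
both words. Missing cells are never imputed: they are reported and the
pipeline refuses to continue.

Directional symmetry is tested by pairing the 325 above-diagonal cells
with their mirrors: a paired t (df = 324) plus a default-prior JZS Bayes
factor (Cauchy scale $\sqrt{2}/2$) computed by numerical quadrature in
`jzs_bf01()`. From the published t statistics this quadrature returns
BF$_{01}$ = 13.1 and 2.42, matching the published 13.14 and 2.43.
Matrices are then symmetrized by triangle averaging regardless of the
Bayes factor (mirroring the source's practice), and RT matrices become
dissimilarities by taking reciprocals.

## Clustering and stability

Rows of the symmetric matrix are treated as 26-coordinate profiles;
`row_distances()` computes Euclidean distances between them, by default
including the diagonal entry as a coordinate (what a generic distance
routine applied to the square matrix does). Ward clustering uses
`stats::hclust`, the tool the original analysis used: the default
`"squared"` variant is `ward.D2` (the Murtagh–Legendre form), `"classic"`
is `ward.D`. The cophenetic correlation is computed against the
row-distance object, the standard `cor(cophenetic(hc), d)` usage; with
the default variant this reproduces the published 0.67 (we get 0.656).
Correlating against the raw matrix entries instead gives 0.53, so the
reference choice is documented and selectable.

One pipeline detail matters for the published cluster memberships: with
the diagonal included, the accuracy dendrogram places only l (not v) with
the base decade; excluding the self-coordinates
(`include_diagonal = FALSE`) reproduces the published accuracy grouping
exactly, with both l and v in the base-decade block. The RT grouping —
{n,z,o,y}, {s,t,r,w,p,q,l,v}, {m,x,k,u}, {a–j} — is recovered under every
variant.

`multiscale_bootstrap_au()` implements approximately-unbiased support
values in-package (no external bootstrap package is assumed): the 26
coordinate columns are resampled with replacement at sizes
$\lceil 26r \rfloor$ for scales $r \in \{0.5, \dots, 1.4\}$, each
replicate is re-clustered, per-node bootstrap proportions are probit-
transformed and fit by weighted least squares to
$z(r) = v\sqrt{r} + c/\sqrt{r}$, and AU $= 1 - \Phi(v - c)$. Edge cases
are explicit: a node seen in every replicate at every scale gets AU = 1
(the probit fit is degenerate at the boundary), a node never seen gets
AU = 0 with a flag, and a single-scale run collapses to the naive
bootstrap proportion. How the original analysis fed a square matrix to
its bootstrap tool is unstated; column resampling of the row-profile
representation is our reading, and with B = 1000 it reproduces AU ≥ 0.90
for all four published clusters.

# The synthetic world

The generator emulates the published design exactly: 24 participants × 5
lists × (130 same + 130 different) trials, every one of the 650 ordered
different pairs once per participant, every same pair 25 times, sessions
split 3 + 2. Its statistical assumptions are the minimal monotone
structure needed to test the pipeline, not a cognitive process model:

* latent dissimilarity $\delta(i,j)$ = informativeness-weighted dot
  mismatch plus a planted four-block term (the published RT clusters),
  rescaled to [0, 1];
* responses through a Gaussian-CDF link with lapse mixture, with
  different-trial difficulty driven by $\delta$ and same-trial fluency by
  letter informativeness (so the same-trial correlations have constructed
  signs: negative for RT, positive for accuracy);
* lognormal RTs, $\log rt = \mu_0 + \mathrm{speed}_p - b\,\delta +
  \varepsilon$, with participant speeds $N(0, \tau)$ — which the adjusted-
  RT normalization must cancel exactly;
* 0.5% of trials replaced by out-of-bounds RTs (the published exclusion
  rate was 0.47%) to exercise the filter.

Defaults were calibrated once against the published summary statistics
and then frozen: slope 10 and criterion 0.3 give different-trial accuracy
0.95 (published 0.966) with a ceiling-heavy cell distribution like the
published accuracy matrix; $\mu_0 = \log 1.45$, $b = 0.35$,
$\sigma = 0.32$, $\tau = 0.2$ give mean RT ≈ 1.49 s (published ≈ 1.54 s)
and an adjusted-RT dissimilarity range (0.77–1.26) close to the published
one (0.78–1.10). Under these defaults both the accuracy- and RT-derived
dendrograms recover the planted partition with ARI ≥ 0.9 in 19 of 20
seeded replicates.

A green synthetic test establishes that the pipeline recovers structure
that is really there, at realistic noise levels; it does not establish
anything about tactile perception, and the generator deliberately omits
sequential-scanning dynamics, session or learning effects, and any
response-time process model.

# Numerical choices and limitations

* Entropies are computed and stored at full precision; rounding to three
  decimals happens only at presentation.
* The simplex uses tolerance 1e-9 with Bland's rule, so it cannot cycle;
  certificates are verified at 1e-6.
* Ward tie-breaking is whatever `stats::hclust` does (deterministic for
  fixed input); we do not re-implement the merge loop, and the test suite
  checks it against an independent Lance–Williams implementation.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; manifests record package version, options and seeds.
* The packaged matrices were transcribed from the published tables; a
  checksum travels in each file's header, and the transcription is
  validated by reproducing the published Spearman, cophenetic, cluster
  and Bayes-factor statistics in the acceptance suite.
* Published quantities that depend on the unavailable raw data
  (trial-level means, the asymmetric pre-symmetrization matrices, exact
  exclusion percentages, letter-frequency correlations) are out of reach
  by construction and are not asserted.
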