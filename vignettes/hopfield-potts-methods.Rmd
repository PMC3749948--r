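---
title: "Hopfield-Potts coevolution analysis: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hopfield-Potts coevolution analysis: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpdca)
```

## The statistical model

A protein family is observed as a multiple-sequence alignment of $M$
homologous sequences over $L$ aligned positions, each position carrying
one of $q = 21$ states (20 amino acids plus the gap).  Covariation
between columns carries structural information, but raw covariance
mixes direct interactions with indirect, transitively propagated ones.
The maximum-entropy model that reproduces one- and two-column
frequencies is a $q$-state Potts model

$$P(a_1,\dots,a_L) \propto
  \exp\Big(\sum_{i<j} e_{ij}(a_i,a_j) + \sum_i h_i(a_i)\Big),$$

whose couplings $e_{ij}$ separate direct from indirect correlation.
The mean-field solution sets the couplings to minus the inverse of the
reduced covariance matrix; that is full-rank direct coupling analysis
(DCA) and needs $\binom{L}{2}(q-1)^2$ coupling parameters.

The Hopfield-Potts model instead constrains the couplings to a low-rank
signed sum over $p$ *patterns* $\xi^\mu$, each an $L \times q$ direction
in sequence space:

$$e_{ij}(a,b) = \sum_{\mu\,\mathrm{attr}} \xi^\mu_i(a)\,\xi^\mu_j(b)
             - \sum_{\nu\,\mathrm{rep}} \xi^\nu_i(a)\,\xi^\nu_j(b).$$

A sequence's *log-score* along a pattern is
$S(\xi, a) = \big(\sum_i \xi_i(a_i)\big)^2$.  Attractive patterns favor
sequences with large log-score; repulsive patterns penalize them.  A
repulsive pattern with two opposite-sign components implements an
XOR-type constraint — the scores for
(neither / first only / second only / both) are $0/1/1/0$ in units of
the squared component magnitude — so it favors joint presence or joint
absence of two residues, the signature of a compensated contact.  An
equal-sign pattern scores $0/1/1/4$ and merely biases co-occurrence
counts; this is why localized *repulsive* patterns are the carriers of
contact information.

In mean-field approximation the optimal patterns are scaled, whitened
eigenmodes of the Pearson correlation matrix
$\Gamma_{ij} = D_i^{-1/2} C_{ij} D_j^{-1/2}$ (with $D_i = C_{ii}$ the
single-site blocks):

$$\xi_i(a) = \sqrt{\lvert 1 - 1/\lambda_k \rvert}\,
  \big(D_i^{-1/2} v_k\big)_i(a),$$

attractive for $\lambda_k > 1$, repulsive for $\lambda_k < 1$.  Each
mode contributes $s(\lambda) = (\lambda - 1 - \ln\lambda)/2$ per unit of
effective sequence count to the log-likelihood, so the $p$ most likely
patterns are those with the largest $s$: both tails of the spectrum
matter, while the bulk near $\lambda = 1$ is irrelevant — the pattern
prefactor vanishes there.  At $p = (q-1)L$ the model is exactly
mean-field DCA (the signed prefactors $1 - 1/\lambda$ resum the inverse
of $\Gamma$); at $p = 0$ it degenerates to a position-specific scoring
matrix.  `interaction_likelihood_ratio()` reports the captured fraction
$\sum_{\mathrm{selected}} s / \sum_{\mathrm{all}} s$; capturing about
90% of it typically retains contact accuracy with far fewer parameters,
which motivates the command-line default `--loglik-fraction 0.9`.

Contacts are scored per position pair by the Frobenius norm of the
coupling block in the zero-sum gauge (double-centering over all $q$
states, gap included), followed by the average product correction
$F^{APC}_{ij} = F_{ij} - F_{i\cdot}F_{\cdot j}/F_{\cdot\cdot}$, with
diagonal-free means.  Pairs closer than 5 positions along the sequence
are excluded by default; contacts in a reference structure are defined
as minimal heavy-atom distance strictly below 8 Å.

## Tunable parameters

* `theta` (default 0.2, dimensionless fraction of $L$): sequences with
  more neighbors within Hamming distance $\theta L$ are down-weighted,
  $w_b = 1/\#\{\text{neighbors}\}$; $M_\mathrm{eff} = \sum_b w_b$.  The
  0.2 default is the value found robust across protein families in
  mean-field DCA practice.  Exact duplicates always count as neighbors,
  so `theta = 0` reduces to duplicate removal.  `hp_pipeline()` also
  accepts `theta = NULL` (unit weights): for alignments *known* to be
  i.i.d. samples — every synthetic family in this package — reweighting
  is not only unnecessary but harmful, because in a small state space
  ($q^L$ comparable to $M$) duplicate down-weighting flattens the
  empirical distribution toward uniform over observed sequences and
  erases the covariation signal.
* `pseudocount_fraction` (default 0.5): the uniform prior mass as a
  fraction of the total, parameterized scale-free in $M_\mathrm{eff}$
  ($\Lambda = \frac{pc}{1-pc} M_\mathrm{eff}$), so 0.5 means half
  counts, half uniform.  Large pseudocounts are standard for mean-field
  DCA; they also guarantee the positive-definite single-site blocks the
  whitening needs.
* `p` or `loglik_fraction`: model rank, directly or via the captured
  likelihood fraction.
* `min_separation` (default 5 positions) and `contact_cutoff`
  (default 8 Å, strict inequality) for evaluation; a stricter 5 Å
  near-contact class can be reported by passing a different cutoff.

## Numerical choices

* Reduced representation: the covariance matrix is built over states
  $1..q-1$, dropping the *last* alphabet state ('Y' in the fixed
  ordering gap, A, C, ..., Y).  The gap deliberately sits first so it
  always survives the projection; gap patterns carry real alignment
  signal.  Predictions are equivalent under the alternative projections
  of this gauge freedom.
* Matrix square roots via symmetric eigendecomposition; a single-site
  eigenvalue below $10^{-12}$ raises an error naming the position and
  advising a pseudocount, rather than silently regularizing.
* Eigenvalues sorted decreasingly; within numerically degenerate groups
  (gap $< 10^{-9}$) any orthonormal basis is accepted.  Couplings are
  provably invariant under that choice (verified by a rotation test);
  per-pattern diagnostics (IPR, $\Delta$) are basis-dependent there and
  selection warns when a degenerate group straddles the cut.  The
  greedy rotation-fixing procedure that picks a canonical basis inside
  degenerate subspaces is not implemented.
* Pattern selection ties (equal $s$) break toward the smaller
  eigenvalue, then the smaller mode index, so outputs are deterministic.
* The typical coupling contribution of a pattern is implemented as
  $\Delta^2 = \sum_{i \ne j}\sum_{a,b} (\xi_i(a)\xi_j(b))^2 /
  (N_\mathrm{eff}(N_\mathrm{eff}-1))$ with $N_\mathrm{eff} = 1/IPR$;
  only its scaling and qualitative ordering across patterns are treated
  as meaningful.
* $s(\lambda)$ is reported per unit $M_\mathrm{eff}$; the common factor
  cannot change rankings or likelihood ratios.
* Fields use the independent-site closure
  $h_i(a) = \ln(f_i(a)/f_i(q)) - \sum_{j\ne i,b} e_{ij}(a,b) f_j(b)$ in
  the gauge $h_i(q) = e_{ij}(\cdot,q) = e_{ij}(q,\cdot) = 0$.  Exact
  field fitting is out of scope: the constrained low-rank model fits
  the frequency constraints only approximately anyway, and contact
  prediction never uses fields.
* Exact enumeration is guarded at $q^L \le 10^6$; beyond that the Gibbs
  sampler (single chain, heat-bath updates in fixed site order,
  compiled; default 1000 burn-in sweeps, thinning 10) is the sampling
  route.  The sampler draws from R's RNG, so `set.seed()` makes every
  alignment reproducible.

## What the generators emulate — and what they do not

`conserved_msa()` reproduces the fully conserved limit, which is
exactly solvable: with a pseudocount the Pearson matrix has three
eigenvalues — one large extended mode ($1 + (L-1)w^2$), the
$(q-2)L$-fold eigenvalue 1, and an $(L-1)$-fold degenerate small
eigenvalue ($1 - w^2$) whose eigenspace admits a basis localized on
site pairs with opposite signs.  At $q=5$, half pseudocount, $w^2 =
2/3$ so the small eigenvalue is $1/3$; the test suite checks the
multiplicities $1$, $(q-2)L$, $L-1$ at tolerance $10^{-8}$ and the
localization of both ends of the spectrum.  `independent_msa()` gives
the no-covariation null (all eigenvalues near 1, all couplings near 0),
and `planted_pattern_family()` samples from a known low-rank model so
the whole inference chain can be tested for parameter recovery: a
single opposite-sign repulsive pattern planted at one site pair is
recovered from $10^4$ sampled sequences with cosine similarity above
0.95 at rank one, and its site pair tops the APC score list.

Real alignments differ in ways these generators deliberately avoid:
phylogenetic correlation between rows (the reweighting heuristic only
mitigates it), non-uniform amino-acid composition, alignment artifacts
such as terminal gap stretches, and many interacting contacts of
heterogeneous strength.  Passing the synthetic suite therefore
validates the estimator chain, not the biology; headline accuracy on
curated families depends on alignment and structure versions and is out
of scope here.

One consequence of the standard pseudocount worth knowing: states never
observed in a column still receive $\Lambda/q^2$ pair mass, and the
mixture of two product measures is itself correlated.  An alignment
occupying only a few of the 21 letters (e.g. a synthetic family written
to FASTA and re-read over the full alphabet) thus shows a strong
extended attractive mode that reflects the prior, not the data.  This
is faithful to the standard DCA preprocessing; for such data either
work at the generator's native $q$ or select enough patterns that the
data-driven repulsive modes are included (the worked CLI examples use
`--p 20`).

## Problem sizes

All tests run on synthetic data generated at call time: enumeration-
backed checks use $L \le 6$, $q \le 4$; sampler-versus-enumeration
checks use $2\times10^4$ sequences; the recovery study uses $10^4$
sequences at $L=6$, $q=4$; the conserved fixture runs at $L=20$,
$q=5$.  These sizes keep every stage exactly verifiable against
brute-force oracles while exercising the same code paths used at
protein scale ($L$ of order $10^2$, $q=21$).
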