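---
title: "Model-free factorization of time-resolved spectra with specnmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free factorization of time-resolved spectra with specnmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A time-resolved spectroscopic experiment produces a matrix $M$
($m \times n$): rows index a wavenumber grid, columns index time points,
and each column is a spectrum recorded at one delay.  When $r$ chemical
species contribute, each column is a non-negative superposition of $r$
pure component spectra weighted by the instantaneous populations, so

$$M \approx W\chi,$$

with $W$ ($m \times r$) holding the pure spectra as columns and $\chi$
($r \times n$) the kinetic traces as rows, both elementwise
non-negative.  Recovering $W$ and $\chi$ from $M$ alone is non-negative
matrix factorization (NMF).  The difficulty is not finding *a*
factorization but choosing among a continuum of them: most established
methods pin down a solution with strong assumptions (normalized rows,
orthogonal or fully separable spectra, Markovian kinetics) that are
physically unjustified for many systems — resonance-Raman intensities,
for instance, make normalization by concentration meaningless.

`specnmf` takes the opposite, bottom-up route.  The only constraints in
the basic configuration are non-negativity of both factors and a
*weighted, optional* preference for small overlap between component
spectra.  No kinetic model enters the separation; kinetic modelling can
be done afterwards on the recovered traces (see `fit_biexponential()`
and `fit_second_order_rates()`).

## Exact factorization through a transformation matrix

A truncated SVD $M = USV'$ with $k \ge r$ components gives
$W_0 = US$, $\chi_0 = V'$ with $W_0\chi_0 = M$ exactly whenever the
numerical rank of $M$ is at most $k$.  For any invertible $r \times r$
matrix $A$,

$$W = W_0 A, \qquad \chi = A^{-1}\chi_0$$

is again an exact factorization, and conversely every exact rank-$r$
factorization of $W_0\chi_0$ arises this way.  The search space is
therefore the $r^2$ entries of $A$ instead of the $(m + n)r$ entries of
the factors, and the data are reproduced exactly by construction —
`reconstruct()` computes $\chi$ by a linear solve (never an explicit
inverse) and enforces a condition cap (default $10^8$) on $A$.

The objective minimized over $A$ is a plain sum of penalties:

* $v_1 = \min(W)^2$ — the squared smallest entry of the spectral
  factor.  As defined, a strictly positive minimum is penalized too: the
  spectral baselines are driven to touch zero.
* $v_2 = -\min(\min(\chi), 0)$ — the magnitude of the most negative
  kinetic entry; zero iff $\chi \ge 0$.
* $v_3$ — spectral overlap, weighted by $a \in [0, 1]$
  (default $a = 0.1$).

Two overlap modes are provided.  The raw Gram-norm
$\lVert\,|W|'|W|\,\rVert_F$ (`"literal_gram"`) is scale-degenerate:
shrinking $W$ while inflating $\chi$ lowers it without changing the
factorization, so it mainly measures the overall scale.  The default
`"normalized_offdiag"` mode sums the cosine similarities of all pairs of
absolute spectra; it is invariant under per-component and global
rescaling and measures overlap only.  The literal mode is retained for
fidelity experiments.

Because the objective is non-convex in $A$, `optimize_transform()` runs
many independent restarts (default 1000; 500 suffice on the benchmark
data) of a derivative-free Nelder–Mead search, each started from an
$A$ filled with i.i.d. uniform entries on $[-1, 1]$ (redrawn while the
condition cap is exceeded), and keeps the overall best.  Each restart
stops at a relative improvement below $10^{-10}$ or $200 r^2$
evaluations; the best point is then polished once with a fresh simplex
and a tenfold budget.  Ill-conditioned candidates receive a large
sentinel value ($10^{10}$) rather than an exception, so the optimizer
simply avoids them.  Ties between restarts keep the first minimum
encountered; with a fixed seed the whole search, including the restart
log, is bit-reproducible.

The number of components $r$ is deliberately a user decision.
`estimate_rank()` suggests the index with the largest singular-value
drop-off ratio $s_i/s_{i+1}$ and flags the suggestion as low-confidence
when no ratio reaches 3, but nothing overrides the user's choice:
testing the stability of results under neighbouring ranks is the
recommended practice, particularly when weak components are suspected.

## Window-based refinement

When prior knowledge locates a species $m$ spectrally — an interval
$[a, b]$ where only species $m$ contributes, or $[c, d]$ where it does
not — `refine_bounded()` re-optimizes $A$ against the window objective

$$v = v_m + v'_m, \qquad
v_m = \sum_{i \ne m}\int_a^b |S_i(f)|\,\mathrm{d}f, \qquad
v'_m = -\sum_{i \ne m}\int_c^d |S_i(f)|\,\mathrm{d}f,$$

with integrals evaluated by the trapezoidal rule on the native grid.
The sign of $v'_m$ is implemented exactly as defined (other species are
*rewarded* for carrying intensity where $m$ is absent); an optional
`penalize_self` mode penalizes species $m$'s own intensity there
instead, for users who prefer that reading.  The search is a single
bounded simplex run started at the stage-one solution $A_f$ and confined
to the element-wise box
$|A - A_f| \le \delta\,(|A_f| + \mathrm{median}|A_f|)$ with
$\delta = 0.2$ by default: the stage-one result is assumed close to the
truth, and the box is also what keeps the negated absence term bounded
below.  Candidates are projected onto the box before evaluation, and the
start point is returned unless a strictly better one is found, so the
window objective never increases.  Several species may carry windows;
their objectives are summed.

## Synthetic benchmarks and what they do (and do not) show

Four generators with known ground truth are built in
(`assemble_dataset()`); all spectra are sums of Lorentzian bands
$A\gamma^2/((f - f_0)^2 + \gamma^2)$ on a 1000-point wavenumber grid
(200–1800, cm$^{-1}$-like) with 172 time points (0–171, arbitrary
units — long enough that the slowest default rate, 0.01 per time unit,
decays visibly).  Band positions are package-defined (the benchmarks'
qualitative description fixes only their character): partly overlapping
bands for the uncorrelated scenario, near-identical band patterns
(shifted by 40 units) for the branched-reaction intermediates B and C, a
spectrally separated product, and low overlap in the mixed-order
scenario.  Every species keeps at least one band free of the others, the
separability the overlap penalty and the window refinement exploit.

* `uncorrelated3` — three smooth, non-negative, pairwise independent
  traces (seeded sums of Gaussian bumps and a logistic drift) that
  follow no kinetic model.
* `branched_first_order3` / `branched_first_order4` — the branched
  first-order scheme A→B→D, A→C→D with
  $k_1 = 0.05$, $k_2 = 0.1$, $k_3 = 0.01$, $k_4 = 0.1$ and
  $I_A(0) = 1$.  In the 3-species variant the educt A is Raman silent:
  it shapes the kinetics but contributes no spectrum.  Two readings of
  the scheme are provided: the `as_printed` variant carries a `+k4*I_D`
  production term in D's equation, which diverges and never consumes C,
  while the default `mass_conserving` variant closes the scheme
  ($\mathrm{d}C/\mathrm{d}t = k_2 A - k_4 C$,
  $\mathrm{d}D/\mathrm{d}t = k_3 B + k_4 C$) so that total concentration
  is conserved.  Both variants have identical A and B traces.
* `second_order3` — the educt branches into B and C, which combine
  bimolecularly: $\mathrm{d}B/\mathrm{d}t = k_1 A - k_3 B C$, with
  $k_1 = 0.05$, $k_2 = 0.025$, $k_3 = 0.1$, solved with `deSolve`
  (lsoda, tolerances $10^{-10}$; verified against a fixed-step RK4
  integrator at a 1000-fold finer step to $10^{-5}$).

Optional i.i.d. Gaussian noise (standard deviation `sigma * max(M)`,
clipped at zero by default to keep the input valid) and a smooth
time-constant background emulate measurement artifacts.  The generators
emulate band superposition, kinetic structure, noise and baselines; they
do **not** emulate instrument line-shape physics (Gaussian/Voigt
convolution), wavelength-dependent resonance enhancement beyond a
per-species amplitude, cosmic-ray spikes, or detector nonlinearity —
passing benchmarks therefore demonstrates the separation machinery, not
robustness to every artifact of real Raman data.

### Two structural degeneracies worth knowing about

Working through the benchmark rate systems exposed two exact linear
dependencies that any factorization method will inherit:

1. In the first-order scheme's `as_printed` reading, B and C decay with the same
   constant $k_3$, which forces $C(t) = (k_2/k_1)\,B(t)$ identically —
   the visible kinetics have rank 2, not 3.  The default
   `mass_conserving` variant restores rank 3.
2. In the mixed-order scheme, with all intermediate concentrations
   starting at zero, $B - C \propto B + C + 2D$ at all times, so the
   three Raman-active traces are linearly dependent *regardless of the
   rates*: the noiseless `second_order3` matrix has numerical rank
   exactly 2.  A 3-component factorization of it is degenerate — the
   transformation-matrix family can only produce spectra inside the
   2-dimensional column space, so the true spectra are unreachable.
   Solutions carrying the *true kinetics* exist (their spectra are the
   rank-2 projections, showing small negative artifacts in the product
   spectrum), but they have markedly higher spectral overlap than
   spurious mixtures, so the overlap criterion does not select them.
   The package generates this scenario faithfully and the evaluation
   tools report honestly what the pipeline recovers; users analyzing
   reactions with such conservation-induced degeneracies should lower
   the rank to the number of *independent* traces, or supply window
   constraints.

## Evaluation under permutation and scale ambiguity

Any exact factorization is invariant under $W \to WC$,
$\chi \to C^{-1}\chi$ for a positive diagonal $C$ and a simultaneous
permutation.  `normalize_for_display()` fixes the scale (unit-maximum
spectra) without deforming traces; `anchor_to_reference()` pins
components to known experimental values instead.
`match_components()` resolves the ambiguity against a ground truth by
exact assignment (enumeration, $r \le 8$) maximizing total spectral
cosine similarity — spectra, not kinetics, because component spectra are
the easier quantity to validate (e.g. against electronic-structure
calculations); scales come from per-component least squares, positive
because both factors are non-negative.  Rate refits
(`fit_biexponential()`, `fit_second_order_rates()`) are invariant to
per-trace rescaling by construction, since recovered traces are
proportional, not equal, to concentrations.

## Preprocessing

Savitzky–Golay smoothing (window 11, order 3 by default) and spline
baseline subtraction are available but **off by default**: whether they
are appropriate depends on the individual dataset, and an overlooked
background otherwise costs one factorization component.  The baseline is
an asymmetrically reweighted smoothing spline (points above the current
fit are down-weighted by a factor 1000 over 20 passes, spline df = 8 by
default) — a conventional choice, since no specific recipe is canonical.
One documented limitation: under heavy-tailed Lorentzian bands the
spline absorbs the overlapping tail pedestal, biasing recovered band
heights by roughly 5–7% on the built-in fixtures; tests assert recovery
at 10%.

## Problem sizes and numerical choices

The test and acceptance workloads use the full-size benchmark matrices
(1000 × 172) with 500 restarts, the scale at which the benchmark
separations converge; small unit fixtures use reduced grids.  Key
constants: condition cap $10^8$; sentinel $10^{10}$; simplex relative
tolerance $10^{-10}$; restart budget $200 r^2$ evaluations (tenfold for
the final polish); rank-suggestion confidence ratio 3; refinement box
$\delta = 0.2$.  Matrices are read and written as tab-separated text
with a time-value header row and the wavenumber grid in the first
column, at 17 significant digits so round trips are bit-exact; negative
intensities are rejected at the door, since the method requires a
non-negative input (difference spectra are out of scope).

## A worked example

```{r example}
library(specnmf)

ds <- assemble_dataset("branched_first_order3", seed = 1)
init <- svd_initialize(ds$M, k = 10)
estimate_rank(init$singular_values)   # suggests 3

fit <- decompose(ds$M, rank = 3, restarts = 500, seed = 1)
m <- match_components(fit$W, fit$chi, ds$W_true, ds$chi_true)

iB <- which(m$permutation == which(ds$species == "B"))
fit_biexponential(fit$chi[iB, ], ds$time_grid)$rate_decay
# ~0.0099: the consumption rate of the intermediate, recovered without
# any kinetic assumption entering the separation
```
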