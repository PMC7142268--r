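---
title: "Dynamics of lethal alleles: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of lethal alleles: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalWF)
```

## The biological setting

This package models one locus with two alleles in a diploid, randomly
mating, dioecious population with discrete generations and census in
adults. The disease-causing allele $a$ is *lethal when homozygous*: the
$aa$ genotype has zero viability, so the selection coefficient is pinned at
$s = 1$ and the relative fitnesses are

$$w_{aa} = 0, \qquad w_{aA} = 1 - h, \qquad w_{AA} = 1 .$$

Because fitnesses cannot be negative, the dominance coefficient is
restricted to $h \le 1$. The biologically interesting neighbourhood is
small $|h|$: $h = 0$ is a fully recessive lethal, small positive $h$ a
partially recessive one, and $h < 0$ means the heterozygote is *fitter*
than the wild-type homozygote (overdominance), which can hold a lethal
allele at frequencies far above anything mutation alone can sustain.
Mutation is one-way, $A \to a$, with probability $u$ per allele copy per
generation (back-mutation of a specific disease lesion is negligible).

Two structural facts drive everything else:

1. **Selection must act on genotypes.** With $s = 1$ the usual
   weak-selection approximation (selection acting additively on alleles)
   is invalid. Lethality, however, *simplifies* the bookkeeping: the $aa$
   genotype never reaches adulthood, so a single adult allele frequency
   still suffices to describe the population.
2. **The adult frequency can never exceed one half.** Every $a$ copy in
   adults sits in a heterozygote, so
   $X = n_{aA} / (2 n_{aA} + 2 n_{AA}) \le 1/2$, independent of model and
   population size. Any valid description of a lethal allele must respect
   this bound; the package enforces it everywhere (construction of a
   frequency outside $[0, 1/2]$ is an error).

## Deterministic dynamics (infinite population)

In an effectively infinite population the frequency evolves as
$X' = X + F(X)$ with the evolutionary force

$$F(x) = \frac{(1-h)u - \left[h + (2-3h)u\right]x - (1-2h)(1-u)x^2}
              {\left[1 + (1-2h)u\right] + (1-2h)(1-u)x}.$$

At $h = u = 0$ this collapses to the textbook lethal-recessive force
$F(x) = -x^2/(1+x)$, whose recursion $X' = X/(1+X)$ has the closed-form
solution $x_t = x_0/(1 + t x_0)$ — used as an exact oracle in the test
suite. The numerator of $F$ is a quadratic in $x$; its admissible root is
the equilibrium

$$\hat X = \frac{2(1-h)u}{h + (2-3h)u + \sqrt{h^2(1+u)^2 + 4(1-2h)u}},$$

valid over the whole range $h \le 1$, $0 \le u \le 1$. Useful limits, all
verified against the exact form in the tests:
$\hat X = \sqrt{u}/(1+\sqrt{u})$ at $h = 0$;
$\hat X \simeq (1-h)u/h$ when $u \ll h^2$ (note that the often-quoted
condition $u \ll h \ll 1$ is *not* sufficient — near $h \sim \sqrt{u}$ the
discriminant is not dominated by $h^2$ and the approximation degrades);
$\hat X \simeq |h|/(1+2|h|)$ for overdominance with $u \ll |h|$, nearly
independent of the mutation rate; and the $u \to 0$ limit is $0$ for
$h \ge 0$ and exactly $|h|/(1+2|h|)$ for $h < 0$.

### Numerical evaluation of the equilibrium

For $h < 0$ the denominator above is a difference of nearly equal
quantities ($-|h| + \sqrt{h^2 + O(u)}$), which loses roughly eight
significant digits at $u = 10^{-8}$, $h = -0.01$. The package therefore
evaluates the conjugate form

$$\hat X = \frac{\sqrt{D} - h - (2-3h)u}{2(1-2h)(1-u)},
  \qquad D = h^2(1+u)^2 + 4(1-2h)u,$$

obtained from the identity $D - \beta^2 = 4u(1-h)(1-2h)(1-u)$ with
$\beta = h + (2-3h)u$; all terms are then additions of positives. For
$h \ge 0$ the direct form is cancellation-free and is used as is. The
result is an exact fixed point: the property suite checks
$|F(\hat X)| < 10^{-12}$ over a thousand random parameter draws (with
realistic mutation rates $u \le 0.1$; at absurd corners such as $u \to 1$
with $|h| \gg 1$, $F$ itself is $O(1)$ and pure rounding exceeds that
bound). The conjugate form stays accurate down to $u = 10^{-12}$, checked
against a 50-digit reference evaluation. The rate of approach to the
overdominant $u \to 0$ limit is $O(u/h^2)$ — the leading correction comes
from expanding $\sqrt{D}$ — and the tests assert that rate.

### Degenerate corners

The single genuinely undefined corner is $u = 1$ *and* $h = 1$: every
gamete then carries $a$ and heterozygotes are lethal too, so no viable
genotype exists and $F$ is $0/0$. The constructor rejects it. $h = 1$
alone (a fully dominant lethal) is admissible and needs no special-casing;
$u = 0$ makes $x = 0$ absorbing.

## The modified Wright-Fisher chain (finite population)

With $N$ adults, the number of lethal-allele copies $n$ (frequency
$x_n = n/2N$) evolves as

$$n' \sim \mathrm{Bin}\!\left(N,\; 2x + 2F(x)\right),
  \qquad X' = n'/2N,$$

which differs from the weak-selection chain
$X' = \mathrm{Bin}(2N, x + F(x))/2N$ in the placement of both factors of
two. Because $\mathrm{Bin}(N, \cdot) \le N$, the bound $X' \le 1/2$ is
structural; the state space is therefore $n = 0..N$ (states above $N$
would be unreachable padding). Both chains share the one-step mean
$x + F(x)$; the lethal-genotype chain's one-step variance is *identically*

$$V(x) = \frac{[x + F(x)]\,[1 - (2x + 2F(x))]}{2N},$$

the diffusion-approximation variance coefficient — an exact moment
identity, not an asymptotic one, and the central assertable fact of the
diffusion module. At low frequency $V(x) \simeq (1-h)(x+u)/2N$: the
population fluctuates like a neutral one of size $N/(1-h)$, and the
fluctuations persist at $x = 0$ because mutation keeps feeding the
boundary. The diffusion density itself has no runtime representation here:
at the census sizes of interest the chain is exact and cheap, so the
package exposes the coefficients only.

The probability $p(x) = 2x + 2F(x)$ is a probability analytically;
excursions beyond $[0 - 10^{-12},\, 1 + 10^{-12}]$ indicate an
implementation bug rather than roundoff and raise an error, while smaller
ones are clamped. The same policy applies to $x + F(x)$ against
$[0, 1/2]$.

### Kernels and stationary distributions

Transition kernels are dense $(N+1) \times (N+1)$ column-stochastic
matrices with binomial-mass columns computed by `stats::dbinom` (log-space
internally, accurate for $N$ in the thousands with $p$ near 0). A guard
cap (default $N \le 10{,}000$) protects against accidental huge
allocations.

The stationary distribution solves $W\pi = \pi$, $\pi \ge 0$,
$\sum_n \pi_n = 1$. For up to 2001 states the package replaces one row of
$(W - I)\pi = 0$ with the normalization constraint and solves densely —
exact to roundoff, with observed residuals
$\lVert W\pi - \pi\rVert_\infty \sim 10^{-17}$ at the sizes used here.
Larger chains fall back to power iteration (tolerance $10^{-14}$, at most
$10^6$ sweeps); the two solvers are cross-checked against each other and,
for $N \le 3$, against brute-force eigen-decomposition. With $u = 0$ the
chain is absorbing at $n = 0$ and uniqueness fails; the degenerate
point-mass distribution is returned with a warning rather than an error.

The stationary mean $E_{\mathrm{stat}}[X]$ is the finite-population analog
of $\hat X$. Across the study grid ($u \in \{10^{-8}, 10^{-5}\}$,
$N \in \{500, 1000, 2000\}$, $h \in \{-0.01, \ldots, 0.01\}$) it is
increasing in $N$ and $u$ and decreasing in $h$, asserted as trend
properties. For $h = 0$ the means are asserted to three decimals in
$\log_{10}$; for $h \ne 0$ only trends and admissibility are asserted,
because the reference values available for those rows are mutually
inconsistent (their own $\log_{10}$ and ratio columns disagree by a factor
of ten in one row, and the infinite-population rows disagree with the
exact equilibrium formula in the same 10x-in-$h$ pattern), while every
other quantity they should be consistent with — the $h = 0$ rows and all
twelve finite-population half-times — agrees with this implementation.

## Dominance schedules and transients

A `dominance_schedule` is piecewise-constant: epoch $i$ starts at
generation $t_i$ (the first epoch at 0) and its $h$ governs the transition
from generation $t$ to $t+1$ for every $t$ in the epoch. The canonical
experiment is an overdominance episode: $h = 0$ until the population is
stationary, a jump to $h^* < 0$ at $t = 0$, reversion at $t = t_f$. For an
infinite population the recursion starts from $\hat X(h{=}0)$; for finite
$N$ the *exact pre-jump stationary distribution* (not a point mass at its
mean) is propagated through the post-jump kernel, since a point mass would
misrepresent the variance the population actually carries at the moment of
the jump.

### Half-times to equilibrium

"Time to equilibrium" is ill-defined for asymptotically converging
dynamics, so the package uses the half-time $T_{1/2}$: the time for the
(mean) frequency to cover half the distance from its initial value to its
final equilibrium or stationary value. Two conventions convert the
discrete crossing into an integer, chosen to match how each quantity is
conventionally tabulated:

* **Deterministic trajectories** derive from a smooth underlying solution,
  so the crossing is located by linear interpolation between the two
  bracketing generations and reported rounded to the nearest generation;
  the real-valued crossing is returned alongside (`t_cross`). A pure
  first-passage count would systematically report the ceiling of the
  crossing instead, and for slow transients (hundreds of generations) the
  two differ by one generation roughly half the time.
* **Finite-population mean trajectories** are reported as the 1-based
  census index of the first crossing, counting the final pre-jump
  generation as generation 1: a crossing after $k$ applications of the
  post-jump kernel is reported as $T_{1/2} = k + 1$. This census-labelling
  convention is how the tabulated finite-population half-times this
  package reproduces are indexed.

Both functions insist that the pre- and post-jump models share $u$, and
refuse degenerate inputs with coinciding endpoints.

For the overdominance episode there are closed-form approximations, valid
under $u \ll |h^*| \ll 1$:
$$T_{1/2}^{\mathrm{rise}} \simeq
  \frac{\ln\!\big(\tfrac{|h^*|}{1+2|h^*|}/\sqrt{u}\big)}{\ln(1+|h^*|)},
  \qquad
  T_{1/2}^{\mathrm{fall}} \simeq
  \frac{\ln\!\big(1 + 2\sqrt{u}/|h^*| - 2u/h^{*2}\big)}{2\sqrt{u}},$$
tested against the exact iteration to within 2% (rise) and 5% (fall) at
$h^* = -0.01$, $u \in \{10^{-8}, 10^{-5}\}$. The fall is faster than the
rise: the restoring force under $h = 0$ acts on a frequency of order
$|h^*|$, much larger than the $O(\sqrt u)$ neighbourhood the rise starts
from. Drift also accelerates both transients (finite-$N$ half-times are
well below the infinite-population ones at matched parameters) because the
finite population starts closer to its (lower) stationary target.

```{r halftimes}
half_time_infinite(lethal_model(1e-5, 0), lethal_model(1e-5, -0.01))
half_time_approx_rise(-0.01, 1e-5)
```

## What the stochastic generator does and does not emulate

The simulator (`sample_trajectory`, `simulate`) *is* the model: binomial
resampling of $N$ adults with genotype-level lethal selection, one-way
mutation, a single unstructured population, constant $N$, and
non-overlapping generations. It deliberately does not emulate features of
real human data: population growth or structure, unequal sex ratio,
inbreeding, overlapping generations, modifier loci, probabilistic
selection among a finite zygote pool, or ascertainment bias in how disease
alleles are observed. Passing tests therefore validate the mathematics of
this idealized model — they say nothing about whether a particular
empirical frequency spectrum is explained by it. All randomness flows
through R's generator, seedable per call and recorded in outputs.

## Numerical choices at a glance

* Equilibrium: conjugate form for $h < 0$; fixed-point residual tolerance
  $10^{-12}$.
* Bound enforcement: clamp within $10^{-12}$ of $[0, 1/2]$ (and $[0, 1]$
  for $p$); larger violations raise.
* Stationary solver: dense up to 2001 states, otherwise power iteration
  ($10^{-14}$, max $10^6$ sweeps); mass renormalized after clamping
  negative roundoff to zero.
* Crossing conventions: interpolation + round (deterministic), census
  index $k + 1$ (finite mean trajectory).
* Equilibrium-reached flag for trajectory summaries: relative deviation
  below $10^{-3}$.
* Tables: $\log_{10}$ values rounded to 3 decimals in formatted output;
  raw full-precision columns retained; TSV written with `%.17g` so values
  round-trip bit-exactly.

Problem sizes in the test suite were chosen to keep the full run around a
minute while still exercising the study design end to end: the complete
$N \le 2000$ stationary grid and all twelve finite half-time rows (cached
across tests), a $10^6$-generation ergodicity run at $N = 50$ compared to
the stationary law through batch-means standard errors, and thousands of
randomized property draws for the bound, moment identities, and fixed
points.

## Known limitations

* No absorption/fixation machinery: with $u > 0$ the chain has no
  absorbing state, and the $u = 0$ degenerate case is handled only as a
  warning-level convenience.
* No inference: the package computes forward dynamics; it does not fit
  $h$ or $u$ to observed disease frequencies.
* The diffusion PDE is not integrated numerically; only its coefficients
  are exposed.
* Selection is treated deterministically within the zygote stage; an
  explicitly probabilistic zygote-selection variant is known to be
  practically indistinguishable at these parameter scales and is not
  implemented.
* The dense stationary solver targets census sizes up to a few thousand;
  for much larger $N$ the power-iteration fallback can converge slowly
  when $u$ is tiny (small spectral gap).
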