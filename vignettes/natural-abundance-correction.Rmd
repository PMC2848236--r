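---
title: "Correcting isotopologue intensities for natural abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting isotopologue intensities for natural abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nacorrect)
```

## The problem

In a stable-isotope tracing experiment a cell culture is fed an enriched
precursor (for example [U-¹³C]-glucose) and the labeling patterns of
downstream metabolites are read out by mass spectrometry. On an
ultra-high-resolution instrument (FT-ICR-MS) every isotopologue of a
metabolite — every species with a distinct count of heavy atoms — is
resolved and identified as its own peak, so for a metabolite with
$C_{max}$ carbons one observes the intensity vector
$I_{M+0}, \ldots, I_{M+C_{max}}$ indexed by the number of ¹³C atoms.

The raw intensities mix two sources of ¹³C: the tracer, which is the
signal of interest, and natural abundance ($NA \approx 0.01109$ for
¹³C), which contaminates every peak with contributions from lighter
species. Because the peaks are isotopically resolved and identified,
this "deisotoping" problem has an exact analytical solution; `nacorrect`
implements that solution, its forward model, and an iterative wrapper
that copes with missing peaks and measurement error.

## The model

A molecule that carries $n$ tracer-derived ¹³C atoms has
$C_{max} - n$ carbons left that can each, independently, be ¹³C by
natural abundance. The fraction of its intensity observed at total heavy
count $k \ge n$ is therefore binomial:

$$B(n, k) \;=\; \binom{C_{max}-n}{\,k-n\,}\, NA^{\,k-n}\,
  (1-NA)^{\,C_{max}-k},$$

where the binomial coefficient counts the mass-equivalent isotopomers.
The total fraction a species loses to heavier peaks is
$B_{sum}(n) = \sum_{k>n} B(n,k) = 1-(1-NA)^{C_{max}-n}$, and the
diagonal identity $B(n,n) = 1 - B_{sum}(n)$ links the two. `nacorrect`
evaluates `loss_fraction_sum()` as the literal series and uses the
closed form inside `build_binomial_table()`; their agreement to within
double rounding is asserted by the test suite.

Two consequences of the binomial form are worth noting because the test
suite leans on them. First, for fixed $n$ the terms over $k$ form a
probability distribution (each row of the table sums to one), so the
forward model conserves total intensity exactly. Second, $B_{sum}(n)$
decreases strictly with $n$ — the more tracer atoms a species carries,
the fewer carbons natural abundance can act on — which produces the
characteristic tapering of contamination toward high label counts, and
its limit: a fully labeled molecule is untouched by the correction.

### The sequential correction and its inverse

Observed and corrected intensities are related by an upper-triangular
linear system; solving it in ascending label-count order gives

$$I_{M+i} \;=\; \frac{I_{M+i;NA}
  - \sum_{x<i} I_{M+x}\,B(x,i)}{1 - B_{sum}(i)},$$

implemented in `correct_sequential()`. The order matters: each step
consumes the already-corrected intensities of all lighter
isotopologues. The forward model `contaminate_sequential()` is the same
system read in the other direction,
$I_{M+k;NA} = \sum_{n \le k} I_{M+n} B(n,k)$, and the two are exact
algebraic inverses — a property the suite checks per element count.

Nitrogen labeling is the same mathematics with $N_{max}$ and the ¹⁵N
abundance substituted. For simultaneous ¹³C/¹⁵N labeling the observed
data form a $(C_{max}+1)\times(N_{max}+1)$ matrix indexed by the two
label counts, each cell is a product-binomial mixture
$B_C(x,i)\,B_N(y,j)$ of lighter cells, and `correct_dual()` /
`contaminate_dual()` perform the corresponding two-dimensional
triangular solve (row-major ascending, so every lighter cell precedes
the one being solved) and its inverse. With one axis of size zero the
dual transforms reduce exactly to the single-label ones.

## The iterative algorithm

Real spectra have two defects the exact solve cannot absorb on its own:
peaks can be missing (below detection or dropped upstream), and
measurement error can push corrected intensities slightly negative.
`iterative_correct()` wraps the solve in a loop; each pass

1. supplements missing peaks — zero on the first pass, thereafter the
   forward-modelled value from the previous pass,
2. runs the sequential (or dual) solve,
3. flattens negative corrected intensities to zero,
4. renormalizes the corrected set to the total intensity of the working
   observed set,
5. forward-models natural abundance back onto the corrected set and
   measures the residual against the genuinely observed peaks.

The loop accepts a pass only if the residual strictly decreased, and
returns the last accepted state; a hard cap (default 100 passes) makes
termination unconditional. On complete, self-consistent input the first
pass already reproduces the single-pass solve and the second pass cannot
improve on it, so the result is the exact solution after one accepted
iteration.

Several details here were genuine design choices:

* **Convergence rule.** There is no tolerance parameter: iteration
  stops at the first pass that fails to strictly improve the residual.
  A tolerance would only mask the geometric convergence the
  supplementation fixed point exhibits (each pass shrinks the residual
  by roughly the supplemented mass fraction; the shipped missing-peak
  test converges in 12 passes).
* **Residual norm.** The aggregate difference is the L1 sum of absolute
  differences by default, with L∞ available via `residual_norm`;
  supplemented peaks are excluded from the residual because they are
  echoes of the model, not observations.
* **First-pass seed.** Missing peaks start at zero: before the first
  solve no model estimate exists, and zero is the only value that does
  not presuppose one.
* **Renormalization basis.** The corrected set is rescaled to the total
  of the *working* observed set, i.e. including the currently
  supplemented values. This is load-bearing: if the basis excluded
  supplemented mass, the forward model would undershoot the observed
  peaks by exactly that mass on every pass, the residual could never
  improve after the first pass, and missing-peak compensation would
  stall at the single-pass answer. With the working-set basis the
  supplemented values and the renormalization converge jointly to the
  self-consistent completion of the observed data.
* **Order of operations.** Negatives are flattened before
  renormalization, so the rescaling accounts for the removed negative
  mass as well as the supplemented peaks.

The final residual, exposed as `quality_residual()`, doubles as a data
quality signal: it is zero precisely when the observed set is exactly
self-consistent under the forward model, and it grows monotonically
with injected perturbation (the suite checks 100 seeded 5%
perturbations). The package deliberately ships no accept/reject cutoff
on it — what residual is tolerable depends on instrument and use.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `na_c` | 0.01109 | fractional ¹³C natural abundance |
| `na_n` | *none* | fractional ¹⁵N natural abundance; must be set explicitly (`default_na_15n()` supplies the IUPAC 0.00364) |
| `precision` | `"double"` | numeric mode of the binomial tables |
| `max_iter` | 100 | iteration cap |
| `residual_norm` | `"L1"` | residual aggregation (`"L1"` or `"Linf"`) |

The ¹³C abundance is configurable because the representative isotopic
composition is revised over time; 0.01109 is the value the correction
is conventionally quoted with. The nitrogen abundance is *never*
assumed: nitrogen and dual modes raise an error until the caller passes
one, so the constant in use is always visible in the analysis script.

## Numerical design

**Double mode and its 270-atom limit.** All table terms are evaluated
in log space (`lchoose` plus log-linear accumulation), so binomial
coefficients never overflow at any size. Double mode is nevertheless
capped below 270 atoms of the labeled element — the regime in which the
implementation's round-trip accuracy is validated — and refuses larger
molecules with an explicit capability error.

**Extended mode.** Larger molecules use compiled 80-bit
extended-precision arithmetic (64-bit mantissa, exponent range to
about $10^{\pm 4932}$), which removes both the underflow of terms like
$NA^{C_{max}}$ and most rounding amplification. One subtlety is
documented here because it shapes the API: the sequential solve
amplifies perturbations of its input by roughly
$(1-NA)^{-C_{max}}$-fold compounded, so at 500 carbons rounding a
spectrum through 53-bit doubles between `contaminate_sequential()` and
`correct_sequential()` alone injects round-trip error near $10^{-11}$.
Extended-mode transforms therefore attach the sub-double remainder of
each intensity to their result (attribute `extended_lo`) and consume it
when present, keeping chained transforms at full extended precision;
with it, the 500-carbon round trip is accurate to about $10^{-14}$
per entry. Extended mode covers single-label transforms; dual-label
matrices are double-precision only, and the table builder caps extended
mode at 2000 atoms (past which term magnitudes approach even the
extended exponent range).

**Error metric.** Round-trip accuracy across molecule sizes is
reported relative to the spectrum scale,
$\max_i |e_i| / \max_i |v_i|$: for random test vectors with entries
arbitrarily close to zero, per-entry ratios measure the conditioning of
the tiny entries rather than the fidelity of the transform. At the
physical ¹³C abundance the per-entry measure is additionally held to
the same $10^{-12}$ bound in the tests.

**Degenerate inputs.** A spectrum that is all-missing, all-zero, or
zero after flattening raises an explicit error rather than returning a
normalized zero vector; a zero-atom molecule gives the identity table.

## The synthetic generator and what passing tests mean

`labeling_scenario()` / `generate_clean_spectrum()` build clean spectra
as delta mixtures: fractions of the metabolite pool at chosen label
counts. The three built-ins — `unlabeled`, `mixed_8_10_12` (equal
thirds at 8, 10 and 12 of 20 carbons, read as the natural rendering of
"equal amounts at three label counts"), and `fully_labeled` — span the
qualitative regimes: pure natural abundance that must collapse to the
monoisotopic peak, partial labeling that shows the tapering of
contamination with label count, and full labeling that must be a fixed
point. `brute_force_contaminate()` is an independent oracle for the
forward model: explicit binomial-mass convolution via a product
recurrence, sharing no code with the analytic path, extended to dual
label as an outer product. `perturb_spectrum()` applies seeded uniform
multiplicative noise, clipped at zero.

The generator emulates *identified, resolved, internally referenced*
isotopologue intensities — the premise of the method. It does not
simulate peak shapes, m/z axes, resolution or identification errors,
detector noise statistics, or abundances of elements other than C and
N; the uniform multiplicative noise model is a plumbing choice for
sensitivity tests, not an instrument model. Passing tests therefore
demonstrate the correctness and conditioning of the correction itself,
not robustness to upstream peak-picking mistakes.

Validation problem sizes, chosen to exercise every claimed regime while
keeping the default suite in seconds: the complete worked four-carbon
example; 20-carbon scenario round trips; a full sweep of element
counts 1–269 in double mode and 500 in extended mode; 1000
random-spectrum oracle comparisons at element maxima up to 40; and a
42-carbon two-block labeling pattern (counts 0–4 and 16–20, equal
tenths — the index structure of a labeled glycerophospholipid) run
through the command-line path end to end.

## Limitations

* Only ¹³C and ¹⁵N are handled, singly or jointly; no third label, and
  no correction for minor isotopes of H, O, P or S (on an
  isotope-resolved instrument those species fall in other, identified
  peaks).
* The correction propagates no intensity uncertainties; the residual is
  a consistency signal, not an error bar.
* Dual-label transforms run in double precision only.
* Inferring the element count from the largest observed index (the
  fallback when `--cmax` is not given) changes the correction when
  trailing isotopologues are genuinely missing — hence the warning; the
  molecular-formula value should be supplied whenever known.
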