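---
title: "Quantifying muscle co-contraction: six indices, their families, and how this package studies them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle co-contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccindex)
```

## The problem

Co-contraction — simultaneous activation of an agonist–antagonist muscle
pair crossing the same joint — is quantified in the movement-science
literature by a zoo of co-contraction indices (CCIs) that are routinely
treated as interchangeable but are not. This package implements six widely
used indices over rectified, amplitude-normalized EMG envelope pairs,
plus the simulation machinery needed to characterize how they behave and
relate: synthetic EMG generators, Chatterjee's rank correlation, and four
studies (surfaces/slices, a correlation-based classification study, and
normalization / comparability / sensitivity scenario experiments).

All indices operate on the pointwise decomposition of the pair into
$\mathrm{EMG}_{low}(t) = \min(\mathrm{EMG}_1(t), \mathrm{EMG}_2(t))$ and
$\mathrm{EMG}_{high}(t) = \max(\mathrm{EMG}_1(t), \mathrm{EMG}_2(t))$.
$\mathrm{EMG}_{low}$ is the "wasted" contraction (cancelled by the opposing
muscle) and $\mathrm{EMG}_{high}-\mathrm{EMG}_{low}$ the "effective"
contraction. At ties both envelopes take the common value, so the effective
contraction is exactly zero there.

## The six indices

With $\int$ denoting integration over the observation window and $N$ the
sample count:

| id | name | definition | range (inputs in $[0,1]$) |
|----|------|------------|---------------------------|
| SR | simple ratio | $\int \mathrm{EMG}_{low} \,/ \int \mathrm{EMG}_{high}$ | $[0, 1]$ |
| FW | Falconer–Winter | $2\int \mathrm{EMG}_{low} \,/ \int(\mathrm{EMG}_1+\mathrm{EMG}_2)$ | $[0, 1]$ |
| TS | Thoroughman–Shadmehr | $\mathrm{mean}(\mathrm{EMG}_{low}) \,/ \max(\mathrm{EMG}_{high}-\mathrm{EMG}_{low})$ | $[0, \infty)$; undefined for identical signals |
| UF | Unnithan–Frost | $\int \mathrm{EMG}_{low} / N = \mathrm{mean}(\mathrm{EMG}_{low})$ | $[0, 1]$ |
| R  | Rudolph | mean over $t$ of $\frac{\mathrm{EMG}_{low}}{\mathrm{EMG}_{high}}(\mathrm{EMG}_1+\mathrm{EMG}_2)$ | $[0, 2]$ |
| T  | temporal | $100 \cdot t_{overlap}/t_{total}$, both signals $\ge$ threshold | $[0, 100]$ % |

They fall into three behavioural families. **Shape-based** indices (SR, FW,
TS) are ratios of the lower envelope to another envelope functional: they
are invariant under joint amplitude scaling and reward waveform similarity
at any amplitude (their constant-signal surfaces carry a ridge along the
diagonal). **Amplitude-driven** indices (UF, R) scale linearly with joint
amplitude and are large only when both muscles are strongly active (their
surfaces peak at $(1,1)$, with maxima 1 and 2). The **temporal** index (T)
depends only on threshold crossings.

## Numerical conventions

**Integration rule.** Every $\int$ is computed as the sample mean, i.e. a
rectangular Riemann sum with the window duration normalized to 1. The
convention cancels out of SR and FW (ratios), is what the explicit $/N$ in
UF means, and is the only reduction under which R attains its documented
maximum of 2 for signals bounded by 1. The sum is deliberately not offered
as a reduction for R: it grows with the number of samples. For non-constant
signals a trapezoidal rule would differ at $O(1/N)$; at the 100-sample
resolution used throughout, this is far below any effect studied here.

**Zero denominators.** Per-sample, the Rudolph ratio at a silent sample
($\mathrm{EMG}_{high}=0$) is defined as 0 — no activity means no
co-contraction, and the numerator vanishes there anyway. Whole-signal zero
denominators are different: SR and FW on an all-zero pair, and TS on
identical signals, are reported as *undefined* (`defined = FALSE`, value
`NA`), never as a sentinel number. This separates "no co-contraction"
(a true 0) from "not computable". TS values are otherwise returned as
computed, however large: near-identical signals legitimately push it toward
infinity, and capping would hide exactly the behaviour that distinguishes it.

**Temporal activity detection** is plain fixed-threshold comparison
(default 0.1 in normalized units, inclusive), with no hysteresis or onset
smoothing. The threshold applies only to the temporal index; for all other
indices any nonzero amplitude counts.

## Chatterjee's coefficient

Dependence between indices is measured with Chatterjee's $\xi$, which
detects nonlinear and nonmonotonic relationships that Pearson and Spearman
miss. We use the ties-aware estimator: sort observations by $x$ (ties among
$x$ broken uniformly at random), let $r_i$ be the number of $y_j \le
y_{(i)}$ and $l_i$ the number of $y_j \ge y_{(i)}$; then

$$\xi = 1 - \frac{n \sum_{i=1}^{n-1} |r_{i+1} - r_i|}{2 \sum_i l_i (n - l_i)}.$$

Without ties this reduces to $1 - 3\sum|r_{i+1}-r_i|/(n^2-1)$, and for a
noiseless functional relationship $\xi = 1 - 3/(n+1) \to 1$. The
coefficient is directional — $\xi(x \to y)$ asks whether $y$ is a function
of $x$ — so the study computes both directions for every ordered index pair
and reports headline associations as the maximum of the two (the
directional table is always emitted alongside). The tie-breaking draw comes
from the seeded study RNG, so runs replay exactly. Index values that are
undefined on a given pair are excluded listwise from that coefficient only,
with the exclusion count recorded.

## Synthetic EMG

The random families emulate amplitude-normalized envelope pairs with a wide
variety of shapes, not physiological EMG: there is no motor-unit model, no
stochastic noise floor, and no smoothing-bandwidth structure. Sinusoid
pairs are $c_1 \sin(c_2(t - c_3)) + c_4$ against
$c_5 \cos(c_6(t - c_7)) + c_8$ with $c_2, c_6 \sim U(0, 10)$ and all other
coefficients $\sim U(0,1)$; polynomial pairs are first- or second-order
with coefficients $\sim U(-1,1)$ and intercepts $\sim U(0,1)$. Every signal
is then full-wave rectified (absolute value, the standard EMG convention —
half-wave clipping would discard waveform structure) and, only if its
maximum exceeds 1, divided by that maximum. No minimum is subtracted:
subtracting the minimum would turn genuinely silent samples into nonzero
activity and change the zero-co-contraction semantics.

Two domain choices are not dictated by the construction and were fixed
once: sinusoids are sampled at 100 points over $[0, 2\pi]$, so frequencies
up to 10 span anything from a fraction of a cycle to ten full cycles;
polynomials over $[0, 1]$, where $U(-1,1)$ coefficients give amplitudes of
order 1. Both choices match the 100-point convention of the scenario
signals.

The deterministic scenarios are piecewise-linear reconstructions of
described conditions — disjoint triangular bursts, constant maximal
activation, partially overlapping bursts, an EMG2 rescaled to peaks
1.4 / 1.0 / 0.6 against a fixed EMG1 (emulating non-normalized,
within-task, and MVC amplitude normalization), and one waveform pair at two
amplitude scales. The exact trace geometry behind the original figures is
not published, so the scenarios are designed to reproduce structure, not
pixels, and every conclusion drawn from them is geometry-independent:
zeros under disjoint support, exact maxima under complete overlap,
monotone responses to the normalization peaks, and scale
(in)variances. In particular the intermediate partial-overlap values
depend on the chosen burst geometry and are reported, but nothing is
asserted about their specific magnitudes. In `norm_A` the ramp-shaped EMG2
crosses the fixed triangular EMG1 about two thirds into the window, so
rescaling it changes both the overlap and the total activity; in `norm_B`
the trapezoidal EMG2 stays above EMG1 for every peak $\ge 0.6$, so only
the total changes.

## Study sizes and reproducibility

The correlation study uses 1000 pairs per family (3000 total) of 100
samples each, the size at which the classification claim is made; the
published bounds (within-shape $\xi > 0.7$, amplitude pair $> 0.9$, all
non-temporal pairs $> 0.5$) are evaluated as the median over five fixed
seeds, which controls Monte-Carlo variation without changing the study
conditions. Surfaces use a $101 \times 101$ grid on $[0,1]^2$, evaluating
the actual index implementations on constant pairs (under constancy every
index reduces to a closed form in the two amplitudes, which the tests
verify to $10^{-12}$). All generators accept seeds and restore the caller's
RNG stream; identical configurations produce byte-identical output tables.

```{r example}
cci_all(gen_scenario("complete_overlap"))
```

## What passing tests do and do not show

The test suite verifies the index algebra exactly (closed forms, scale
laws, brute-force oracles at small $n$), the $\xi$ estimator against
enumeration over all permutations at $n \le 6$, and the studies'
qualitative claims. Because all inputs are synthetic and noise-free, these
results characterize the *formulas*, not measurement practice: nothing
here speaks to electrode placement, filtering and enveloping choices,
onset-detection robustness, or how the indices behave under realistic EMG
noise. The temporal index in particular is tested only with the fixed
0.1 threshold; its known sensitivity to onset/offset detection methods is
out of scope. Extending the comparisons to experimental EMG across tasks
and populations is the natural next step and deliberately not attempted
here.
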