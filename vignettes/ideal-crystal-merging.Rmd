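---
title: "Ex-Gaussian diagnostics and Ideal Crystal merging: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ex-Gaussian diagnostics and Ideal Crystal merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exgmerge)
```

## The statistical problem

Serial femtosecond crystallography records one still diffraction snapshot per
microcrystal. A unique Bragg reflection is therefore observed many times —
once per crystal that happened to satisfy its diffraction condition — under
enormous variation in crystal size, quality and orientation offset. Two
facts make the resulting per-reflection intensity histograms unusual:

1. most observations sample the diffuse/background response: their most
   frequent value coincides with that of systematically absent reflections,
   which by symmetry carry no Bragg intensity at all;
2. a minority of observations, from well-diffracting crystals near the top
   of their rocking curve, form a long right tail.

A Gaussian model, whose mean is the classical merged intensity, conflates
these two components. `exgmerge` instead models each reflection's unmerged
intensities $x_1,\dots,x_M$ as draws from an **exponentially-modified
Gaussian** (ex-Gaussian), the distribution of $N(\mu,\sigma^2) +
\mathrm{Exp}(\tau)$:

$$f(x;\mu,\sigma,\tau) = \frac{1}{\tau}
  \exp\!\left(\frac{\sigma^2}{2\tau^2} - \frac{x-\mu}{\tau}\right)
  \Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right).$$

$\mu$ and $\sigma$ (counts) locate and scale the Gaussian background
component; $\tau$ (counts) is the mean of the exponential tail and carries
the Bragg signal. The Gaussian is the $\tau \to 0$ boundary of the family.

### Numerical evaluation

The density is evaluated entirely in log space using `pnorm(log.p = TRUE)`.
One further guard matters: for $z = (x-\mu)/\sigma - \sigma/\tau \ll 0$ the
three terms $\sigma^2/2\tau^2$, $-(x-\mu)/\tau$ and $\log\Phi(z)$ are each
$O(z^2)$ and cancel to $O(u^2)$, $u = (x-\mu)/\sigma$. In doubles that
cancellation destroys all precision once $\sigma/\tau \gtrsim 10^8$ (the
remainder is below the floating-point granularity of the large terms), and
an optimizer will happily exploit the resulting spurious zeros. For
$z < -20$ the cancellation is therefore done analytically with the
asymptotic expansion of $\log\Phi$:
$\log f = -\log\tau - u^2/2 - \log(-z) - \tfrac12\log 2\pi +
\log(1 - z^{-2} + 3z^{-4} - 15z^{-6})$, accurate to $\sim 10^{-9}$ at the
branch point and improving rapidly. The same branch is used in the compiled
kernel and the R reference implementation; tests pin both to a quadrature
convolution oracle.

Quantiles are obtained by bracketed Newton iteration on the CDF to
$|F(x)-p| \le 10^{-9}$, vectorized across posterior samples.

## Per-reflection fitting and model choice

Observations are mapped to the asymmetric unit of Laue group mmm
($(h,k,l) \mapsto (|h|,|k|,|l|)$; Friedel pairs merged, anomalous signal
deliberately ignored), d-spacings computed from the orthorhombic metric, and
P2~1~2~1~2~1~ screw-axis absences flagged (axial reflection with an odd
index). Only this space group is supported; anything else errors out rather
than silently mis-grouping.

Gaussian MLE is closed-form ($\hat\mu = \bar x$, $\hat\sigma^2 =
\sum(x-\bar x)^2/n$). The ex-Gaussian MLE uses Nelder–Mead over $(\mu,
\log\sigma, \log\tau)$ — the log parameterization enforces positivity
without constrained optimization. Starts come from the standard moment
recipe $\tau_0 = (\text{skew}/2)^{1/3} s$ clamped to $[0.05s, 5s]$, with
two perturbed restarts plus a near-Gaussian start $(\bar x - \epsilon,
\sqrt{s^2-\epsilon^2}, \epsilon)$, $\epsilon = 10^{-7}s$. The last start
guarantees **sub-family dominance**: the returned $-\mathrm{LogL}$ never
exceeds the Gaussian optimum beyond $\sim 10^{-9}$, so the likelihood-ratio
statistic cannot go negative by more than optimizer noise (it is clamped at
0 regardless).

Model preference per reflection uses $\chi^2 = 2(\mathrm{nll}_g -
\mathrm{nll}_{exg})$ against the $\chi^2_1$ upper 5% point, 3.84. Because
$\tau > 0$ lies on the parameter boundary, the asymptotic null is really the
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ and 3.84 is conservative; we
replicate the published rule and treat the 5% rate as an upper bound.
Measured consequences, worth knowing when reading diagnostics:

* type-I rate at $n = 60$ is ~0–2%; at $n = 5$–$10$ the $\chi^2_1$
  asymptotics fail and the rate rises to ~8–10%, so preference calls on
  very-low-multiplicity reflections are unreliable in both directions;
* power at the corner ($\tau = 2\sigma$, $n = 50$) is ~0.83, reaching
  $\ge 0.9$ from roughly $\tau = 2.5\sigma$, $n = 60$ onward.

Shell diagnostics use equal-count shells (default 20) ordered from low to
high resolution; equal counts stabilize preference fractions where
equal-width-in-$q$ shells would starve the extremes. Absences are excluded
from preference statistics but reported separately.

## The Ideal Crystal rule

Rather than asking "what is the typical observation?", merging asks "how
high can the Bragg intensity plausibly be?". Per reflection:

1. posterior over $(\mu, \sigma, \tau)$ under a flat prior, approximated by
   random-walk Metropolis: 50 000 samples, 40 000 burn-in, thinning 10
   (1000 retained) — the published settings, all configurable;
2. for each retained sample, $I_{\text{ideal}}$ is the intensity where that
   sample's CDF reaches `critical_cdf` (default 0.95);
3. the merged intensity is $\mathrm{mean}(I_{\text{ideal}})$ and its
   uncertainty $\mathrm{sd}(I_{\text{ideal}})$.

Decisions the published procedure leaves open, and what this package does:

* **Prior bounds** (must be finite for a proper uniform prior):
  data-adaptive boxes $\mu \in [\min x - 5R, \max x + R]$ ($R$ = range),
  $\sigma \in [10^{-3}s, 10s]$, $\tau \in [10^{-3}s, 20s]$. Wide enough
  that the likelihood, not the box, dominates; auto-widened with a warning
  if the MLE falls outside.
* **Proposal**: independent Gaussian steps on $(\mu, \log\sigma,
  \log\tau)$. Sampling in log space requires the Jacobian
  $\log\sigma + \log\tau$ in the target so the prior stays uniform on the
  natural scale. Step sizes adapt toward an acceptance rate in [0.2, 0.5]
  during burn-in only and are frozen afterwards, preserving detailed
  balance in the retained samples.
* **Start**: the MLE (= MAP under a uniform prior).
* **Low multiplicity**: reflections with $M < 5$ cannot support a
  three-parameter fit; they fall back to a Gaussian-posterior quantile at
  the same `critical_cdf` and are flagged `"fallback"`. $M < 3$ or
  zero-variance groups are flagged `"degenerate"` and report the sample
  mean/SD. The published work does not say how such reflections were
  handled; flags make the choice auditable downstream.
* **Reflections whose LRT prefers the Gaussian** are still merged through
  the ex-Gaussian posterior (the Gaussian is inside the family); LRT status
  is available in the diagnostics table.
* **Determinism**: each reflection's chain gets a seed derived from the
  dataset seed and the reflection's position, so merged output is
  bit-reproducible and independent of evaluation order.

Correctness of the sampler is tested against a brute-force grid posterior
(81³ points over an explicit prior box at $n = 30$): posterior means agree
within 5% of the posterior SD, using a long chain so Monte Carlo error sits
below that tolerance.

## Wilson scaling and the correction factor

The Wilson fit regresses $\ln\langle I\rangle$ on $q = 1/d^2$ over
equal-count shells with $B = -2 \times$ slope — equivalent to the textbook
$\ln I = \ln C - 2B\sin^2\theta/\lambda^2$ since $\sin^2\theta/\lambda^2 =
1/(4d^2)$. The convention is pinned here because the source procedure never
states one; only shells with positive mean intensity enter.

Quantile-based merging compresses the resolution falloff (a flatter Wilson
plot), so a resolution-dependent correction
$f(q) = b - (b-1)q^2/q_n^2$ — $f(0) = b$, $f(q_n) = 1$, non-increasing for
$b \ge 1$ — multiplies intensities and sigmas; $b$ values 1.05 and 1.19 were
the published settings for matching two external references. Since those
references chose $b$ by matching Wilson B by hand, `solve_b_for_wilson()`
root-finds $b$ for a target B, making that step reproducible.

## What the synthetic generator does and does not emulate

`simulate_dataset()` states this world (defaults chosen once, then frozen):

* the published orthorhombic cell (57.9, 84.8, 384.3 Å) to a 3.5 Å limit;
* multiplicities uniform on 5–160, matching the observed M range;
* a shared background $N(0, 600^2)$ counts;
* non-absent reflections: background **plus** an exponential tail of mean
  $\tau(hkl) = S e^{-B/(2d^2)} F_{hkl}$ with $S = 6000$, $B = 30$ Å² and
  $F_{hkl}$ log-normal (sdlog 0.5) — so fitted magnitudes land in the
  observed ranges ($\sigma_{exg} \approx 500$–1200, $\tau_{exg} \approx
  700$–9000) and $\tau$ follows a Wilson-like falloff;
* absences (5% of reflections, drawn from the axial odd-index set): pure
  background;
* synchrotron mode: near-symmetric $N(\mu(hkl), (0.1\mu + 120)^2)$ with
  Wilson-decaying mean.

Not emulated: partiality, per-image scale variation, detector noise
structure, spot-shape effects, and — deliberately — any hit/miss mixture:
every non-absent draw carries its exponential tail, matching the model
class that is fitted. One measurable consequence: the modal observation of
a pure ex-Gaussian sits $\approx \sigma z^*$ above background, where
$\phi(z^*)/\Phi(z^*) = \sigma/\tau$ (about $1.5\sigma_b$ at $\tau =
5\sigma$), so the generator reproduces the "most frequent observations are
background-like" diagnostic only approximately, not as exact mode equality.
A green end-to-end test therefore establishes that the pipeline recovers a
known Wilson-decaying tail ranking (Spearman > 0.9) and B within 25% — not
that it would survive every pathology of real SFX data.

## Known limitations and quirks

* **Identifiability**: when $\tau \gg \sigma$ the Gaussian component is
  buried under the tail; at $M \approx 100$, $\mu$ and $\sigma$ carry
  median relative errors of ~25% (while $\tau$ stays ~10%), shrinking to
  <5% at $M = 10^4$. This is Fisher information, not an optimizer defect.
* **Printed d-spacings**: the published parameter table's resolutions for
  its example reflections (and its even-index "absent" axial rows) are
  consistent with the synchrotron cell's shorter c axis, not the stated
  XFEL cell; this package computes from the cell you give it and flags only
  genuine odd-axial absences.
* **Centric/epsilon effects** are out of scope: no epsilon factors, no
  centric-class distributions, no French–Wilson truncation.
* Extensions documented but not implemented: empirical-Bayes priors,
  absence-informed dynamic range, median/MAD reporting, hit/miss mixture
  generation, other skewed families.
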