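# exgmerge

Ex-Gaussian intensity diagnostics and Bayesian "Ideal Crystal" merging for
serial femtosecond crystallography (SFX).

## The problem

SFX collects one still diffraction snapshot per microcrystal, so each unique
Bragg reflection is observed tens to hundreds of times across crystals of
wildly varying size and quality. Classical merging assumes the observations
of a reflection scatter symmetrically about their true intensity and reports
their mean. In SFX that assumption fails: most observations sample the
diffuse/background response (their mode coincides with that of
systematically absent reflections, which carry no Bragg signal at all),
while a minority of well-diffracting crystals produce a long right tail.
The intensity histogram of a reflection is therefore strongly skewed and
the mean is a poor summary of the Bragg signal.

`exgmerge` is for crystallographers and methods developers who want to

1. **diagnose** that skewness per reflection, by fitting both a Gaussian
   N(μ, σ) and an exponentially-modified Gaussian (ex-Gaussian) to each
   reflection's unmerged intensities and applying a nested likelihood-ratio
   test, and
2. **merge** the data under a model that asks "how high can the Bragg
   intensity be?" rather than "what is the typical observation?".

## The model

The ex-Gaussian is the distribution of N(μ, σ²) + Exp(τ): a Gaussian
background/diffuse component convolved with an exponential Bragg tail of
mean τ. Its density is

    f(x; μ, σ, τ) = (1/τ) exp(σ²/2τ² − (x−μ)/τ) Φ((x−μ)/σ − σ/τ)

with Φ the standard normal CDF (evaluated in log space for stability).
Per reflection:

- **MLE fits** — Gaussian closed form; ex-Gaussian by Nelder–Mead simplex
  over (μ, log σ, log τ) from moment-based starts.
- **Model selection** — χ² = 2(−LogL_gauss − (−LogL_exgauss)), referred to
  the χ²₁ cutoff 3.84 at the 5% level (the Gaussian is the τ→0 boundary of
  the ex-Gaussian family, making the test conservative).
- **Ideal Crystal merging** — random-walk Metropolis over (μ, σ, τ) with
  uniform priors: 50 000 samples, 40 000 burn-in, thinning 10 (1000
  retained). For each retained sample, I_ideal is the intensity where that
  ex-Gaussian's CDF reaches 0.95; the reflection's merged I is mean(I_ideal)
  and its σ is sd(I_ideal).
- **Scaling** — Wilson plot (ln⟨I⟩ vs 1/d², B = −2·slope) and the
  resolution-dependent correction f(q) = b − (b−1) q²/q_n².

Symmetry support is the orthorhombic space group P2₁2₁2₁ (Laue group mmm,
Friedel pairs merged; screw-axis absences: odd axial indices).

## Worked example

```r
library(exgmerge)

spec <- simulation_spec(seed = 42)          # 200 reflections, SFX mode
sim  <- simulate_dataset(spec)
groups <- group_observations(sim$observations, spec$cell)

diag <- fit_reflections(groups)             # per-reflection fits + LRT
ok <- diag[!diag$is_absent & diag$fit_ok, ]
mean(ok$prefers_exgauss)
#> [1] 0.9263158

merged <- merge_dataset(groups, mcmc_settings(seed = 42))
#> merge_dataset: 190 reflections merged (0 fallback, 0 flagged), 10 absences excluded

m <- merge(merged, sim$truth, by = c("h", "k", "l"))
cor(m$intensity, m$tau_true, method = "spearman")
#> [1] 0.9671045

wilson_fit(merged, spec$cell)$wilson_b      # B_true = 30 in the generator
#> [1] 32.06483
```

92.6% of the simulated Bragg reflections prefer the ex-Gaussian model (the
generator always adds an exponential tail to non-absent reflections); the
merged idealized intensities rank-correlate at 0.97 with the true
per-reflection tail scale, and the Wilson B recovered from the merged data
(32.1 Å²) is close to the generator's 30 Å².

## Command line

```sh
exgmerge simulate --n-reflections 200 --mode sfx --seed 1 --out obs.tsv --truth truth.tsv
exgmerge diagnose --input obs.tsv --outdir out/
exgmerge merge    --input obs.tsv --critical-cdf 0.95 --samples 50000 --burn 40000 --thin 10 --seed 1 --outdir out/
exgmerge wilson   --input out/merged.hkl --out wilson.tsv
exgmerge correct  --input out/merged.hkl --b 1.05 --out corrected.hkl
```

(the launcher installs to `system.file("exec", "exgmerge", package = "exgmerge")`;
all subcommands are equally reachable as `exgmerge::exg_main(c("merge", ...))`).

Input dialects: a flat whitespace table `frame_id h k l I [sigma]`, or a
"stream-lite" format of per-frame blocks delimited by
`BEGIN_CHUNK <frame_id>` / `END_CHUNK` containing `h k l I [sigma]` rows.
Merged output is a plain-text hkl file (`h k l I sigma multiplicity`,
CNS/SHELX-adjacent layout) with the cell and space group in header comments.

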