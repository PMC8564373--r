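---
title: "Combinatorial binary barcoding: models, statistics, and color calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial binary barcoding: models, statistics, and color calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The labeling model

In a combinatorial binary (Bitbow-style) cassette, each of N fluorophore
modules is flanked by a pair of inverted, mutually incompatible FRT sites.
Transient flippase activity flips each module into an ON or OFF orientation,
independently of the others, and the outcome is then stable. A labeled cell
therefore displays one of the `2^N - 1` nonzero binary codes; the all-zero
state produces no fluorescence and is invisible. With five spectrally
separable fluorophores targeted to one, two, or three subcellular
compartments (membrane, nucleus, Golgi), N is 5, 10, or 15 and the code
capacity is 31, 1,023, or 32,767 (`code_capacity()`).

Codes are written as groups of five 0/1 digits in the fixed fluorophore
order mAmetrine (A), mTFP1 (T), mNeonGreen (G), mKO2 (O), tdKatushka2 (K),
one group per compartment in the order membrane, nucleus, Golgi:
`"01000-00000-00001"` has membrane-mTFP1 and Golgi-tdKatushka2 ON. This
ordering is a package-wide convention, never inferred from input, and the
lexicographic order of code strings is the global tie-break used everywhere
a deterministic ordering is needed.

**Independence assumption.** All probability machinery assumes modules
recombine independently — the design motivation for using incompatible FRT
sites. Correlated recombination models are out of scope; if inter-module
correlation were present, `build_code_distribution()` would mis-state the
code probabilities while the purely empirical statistics
(`cluster_collision_summary()`, `shannon_entropy()`) would remain valid.

## From module frequencies to code probabilities

Each module i has an ON probability `p_i` ("module frequency"). Under
independence the probability of bit pattern x is
`prod(p_i^x_i * (1-p_i)^(1-x_i))`; conditioning on "at least one bit ON"
(the only observable cells) and renormalizing gives the code distribution
over the nonzero pool (`build_code_distribution()`).

Observed per-slot ON fractions in imaging data are *conditional* marginals
`m_i = p_i / (1 - prod(1 - p_j))`, slightly inflated relative to `p_i`
because the unlabeled state is never seen. `decondition_marginals()` inverts
this map by the fixed-point iteration `p <- m * (1 - prod(1 - p))` started
at `p = m`, stopping when the reproduced marginals match within 1e-9
(iteration cap 10,000; infeasible marginals — e.g. all `m_i` far smaller
than is consistent with any labeled population — are reported as
non-convergent with the residual). By default, user-supplied frequency
tables are interpreted as unconditional `p_i`; pass
`conditional_marginals = TRUE` to apply the inversion first. The convention
matters in the percent range, not qualitatively.

## Collision statistics

"Collision rate" is standardized package-wide as the expected fraction of
draws that repeat an earlier draw when n lineages draw codes i.i.d.:
`E[(n - #distinct)/n]`. For a uniform pool of b codes this is the classical
birthday-problem closed form

```
c = n - b * (1 - ((b - 1)/b)^n),    rate = c / n
```

(`expected_collision_rate_uniform()`), which at n = 200 gives 84.5%, 9.1%,
and 0.3% for b = 31, 1,023, 32,767. For an arbitrary distribution the exact
expectation is `c = n - sum_i(1 - (1 - p_i)^n)`
(`expected_collision_rate_general()`), which reduces to the closed form at
`p_i = 1/b` and is verified in the tests against brute-force enumeration of
all `b^n` draw tuples on tiny pools. `simulate_collision_rate()` is the
Monte Carlo counterpart (draw, count repeats, average), with a default
replicate schedule of 100,000 replicates below 100 lineages, 1,000 up to
1,000, and 10 above that.

The *experimental* cluster statistic — the fraction of clusters in a brain
whose code is shared by another cluster (`cluster_collision_summary()`) —
is a different functional of the same sampling process and is deliberately
kept under a different name; its per-brain output also includes
`repeat_rate = (clusters - distinct codes)/clusters`, the quantity the
analytic machinery predicts, so the two routes can be compared like for
like. Experimental summaries are computed within each brain and then
summarized as mean ± SD across brains; simulations pool a single draw of n
lineages. With a single brain the SD is reported as `NA` rather than a
fabricated 0.

**Whitelisting.** Recombination bias concentrates probability on a few
codes (in practice those with the most recombinogenic module ON), and those
codes cause most collisions. `whitelist_exclude_top(dist, m)` removes the m
most probable codes (probability ties broken lexicographically, so
whitelists are reproducible across platforms); excluding 67 or 767 codes
from the 15-bit pool leaves 32,700 or 32,000. In simulations the default
whitelist semantics is renormalization — sampling conditioned on the
whitelist, which is distributionally identical to rejection-resampling —
with a `"discard"` option that instead drops non-whitelisted draws from the
tally (fewer effective draws per brain). Renormalization is the default
because conditioning is what the analytic oracle computes exactly.

## Experiment sizing (coupon collector)

`simulate_animals_needed()` estimates how many animals are required until
every one of L lineages has been validly sampled at least once. Per animal,
each not-yet-sampled lineage activates independently with `activation_rate`
(48.08% is the dense-labeling preset, from 577 clusters over six brains of
~200 lineages; 1% and 0.5% are sparse single-color presets — both are kept
because the two figures come from different parts of the original analysis,
and the discrepancy is surfaced rather than resolved). An activated lineage
draws a code; the sample counts only if the code is on the whitelist, since
a high-frequency code cannot be confidently assigned to a lineage. A
non-whitelisted draw does not block later sampling of that lineage.
Already-sampled lineages are not re-drawn — equivalent in distribution to
re-drawing, and cheaper.

The number of animals for one lineage is geometric with success probability
`q = activation_rate x whitelist mass`, so the total is the maximum of L
i.i.d. geometrics with expectation `sum_{a>=0} [1 - (1 - (1-q)^a)^L]`
(`expected_animals_analytic()`, truncated when the tail term drops below
1e-12). The simulation's default of 500 trials matches the procedure it
implements; the test suite uses 10,000 trials where it checks simulation
against the analytic value within 3 standard errors.

## Color calling

The imaging chain converts raw C-channel intensities (C >= 5; detectors
often bin 32 channels into 5 tracks, so C is configurable with default 5)
into binary codes:

1. **Unmixing.** Per pixel, solve `M a ~ y` against the reference mixing
   matrix M (columns = single-fluorophore spectra, unit-sum-normalized;
   full column rank required, rank deficiency is an error that reports the
   condition number). The default solver is nonnegative least squares —
   abundances are physical — implemented as a batched unconstrained solve
   with per-pixel active-set refinement only where the unconstrained
   solution goes negative (the two coincide elsewhere). Plain least squares
   with clamping is available via `method = "ls"` since the exact solver of
   the original plugin is unspecified.
2. **Smoothing.** Per node of the neuron trace, the median over the node's
   3x3x3 voxel neighborhood, then a centered rolling mean of 10 samples
   along trace order. The rolling window is clipped (shrunk) at the trace
   ends, so output length equals input length and a window that engulfs a
   short series returns its global mean. Both steps are order statistics or
   averages of subsets, so smoothing never widens a channel's range.
3. **Normalization.** Each node's 5-vector is divided by its sum, putting
   bright and dim pixels on the same color scale. Nodes whose summed
   intensity falls below a floor are flagged background; in the volume
   pipeline the floor defaults to 1% of the 99th percentile of summed node
   intensities.
4. **Bit calling.** Per cell, channels are aggregated by the median over
   non-background nodes (robust to brightness gradients; mean available),
   and a bit is ON when the aggregate meets or exceeds the channel
   threshold — ties count as ON. Thresholds are fixed (default 0.1) or
   automatic: Otsu's between-class criterion per channel across all cells,
   computed on `log10(share + 0.01)` because ON shares are broad and
   right-skewed (they depend on how many other bits are ON and on
   expression level) while OFF shares cluster near zero; on the raw scale
   the variance criterion tends to cut inside the ON population. The fitted
   cut is kept only when it separates two substantial classes (each >= 2%
   of cells) whose means are at least four pooled within-class SDs apart —
   tail cuts of a unimodal sample reach about three — otherwise the channel
   falls back to the fixed threshold. Reported margins
   `|aggregate - threshold|` quantify per-channel confidence.

`consistency_stats()` summarizes soma-versus-neurite agreement as the
per-channel absolute difference of median normalized intensities, with the
maximum as a scalar distance, and `neurite_assignment()` checks that each
neurite's color maps back to its own soma under nearest-centroid
assignment. Note that cells that happen to share a code can only be
distinguished by expression level, so perfect assignment is only expected
when codes (or at least colors) are distinct.

## The synthetic-data module

`gen_module_frequencies()`, `gen_cluster_table()`, `gen_mixing_matrix()`,
and `gen_labeled_volume()` generate every input the pipeline consumes, with
ground truth attached, and each is a pure function of its seed and
configuration. The frequency preset encodes the empirically reported bias
ordering — the mNeonGreen module most frequently ON, then mAmetrine, then
tdKatushka2, with mTFP1 and mKO2 similarly lowest — with base values
(0.35, 0.12, 0.55, 0.10, 0.25) in slot order A, T, G, O, K and a ±0.02
seeded jitter per compartment group; the base values were chosen once as a
plausible magnitude for that ordering and are not fitted to any dataset.
Cluster tables activate each lineage per brain with the configured rate
(default 0.4808, 6 brains, 200 lineages per brain) and assign one code per
activated lineage, matching the observation that a neuroblast's
recombination outcome is shared by its cluster and stable over time;
within-lineage code heterogeneity is deliberately not modelled.

Synthetic volumes render a spherical soma (radius 2.2 voxels) and a
straight 5-voxel-wide neurite per cell on a grid, with per-cell ON-bit
amplitudes drawn log-normal (sdlog 0.3 around amplitude 1) — expression
level varies between cells and must not change the called code — mixed
through a diagonal-dominant matrix with configurable bleed-through, plus
Gaussian detector noise (clipped at zero). The geometry is intentionally
minimal: enough structure to exercise the 3x3x3 median and the path
smoothing, no more. What passing tests on these volumes shows is that the
calling chain is correct under its stated noise model; it does not show
robustness to unmodelled properties of real data — antibody amplification,
expansion distortion, depth-dependent attenuation, chromatic misalignment,
tracing errors, or spatially correlated background.

## Problem sizes and numerical conventions

The test suite and analysis scripts use sizes chosen to make Monte Carlo
agreement checks decisive at 3 standard errors while keeping runs short:
10,000 trials for coupon-collector comparisons, 10,000–100,000 replicates
for collision simulations (the small-system tier of the replicate schedule),
a ~50,000-cluster table for ±0.01 parameter recovery, and 200-cell volumes
(60 noiseless) for end-to-end calling. Percentages are printed at one
decimal with round-half-even. Entropy is reported in bits (log base 2),
consistent with the binary-bit framing; `0 * log(0)` terms contribute zero.
Probability sums are validated to 1e-12; unmixing exactness in the
noiseless case is asserted at 1e-9.

## Known limitations

- All distribution-based machinery inherits the module-independence
  assumption.
- The collision and sizing models treat lineage codes as i.i.d. draws;
  spatial structure (neighboring lineages, hemisegment repeats) is ignored.
- Auto-thresholding needs a population of cells per channel with both
  states represented; single-cell calling must use fixed thresholds.
- The synthetic volumes are not anatomically realistic, and the TIFF/SWC
  writers target interchange, not microscope-vendor metadata fidelity.
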