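---
title: "Methods: network inference from seam-cell transcript counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference from seam-cell transcript counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

seamnet infers a small gene regulatory network (GRN) among three
*C. elegans* seam-cell transcription factors — ELT-1, EGL-18 and
CEH-16 — from smFISH transcript counts measured per cell in wild-type
and hypomorphic mutant backgrounds. This vignette is the package's own
account of the models and of every numerical and design choice that a
maintainer would want to know about. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Data model and summary statistics

The unit of observation is one gene in one cell of one animal: a
record `(gene, genotype, timepoint, animal_id, cell_id, count)`, with
`count` a non-negative integer (mRNA spots). `(animal_id, cell_id,
gene, timepoint)` is unique; analyses restrict to the V1–V4 seam-cell
lineages by default.

`summarize_expression()` resamples cells with replacement within each
gene × genotype group (`n_boot` times, default 1000) and reports

* `mu` — the mean of the per-resample means, and
* `sigma` — their standard deviation, i.e. a bootstrap standard error
  of the group mean.

**Why the SE of the mean and not the SD of counts:** the downstream
fit criterion compares *model steady states* to *data means*, so the
natural uncertainty is that of the mean. The bootstrap unit is the
cell (not the animal): stratification by animal is not modelled, which
slightly underestimates `sigma` when extrinsic noise dominates —
a known limitation shared with resampling the raw data directly.

Noise diagnostics use the sample (n−1) variance convention: Fano
factor `var/mean` (1 for Poisson), coefficient of variation `sd/mean`,
and the paired-cell correlation — the Pearson correlation of the same
gene between the two lowest-lineage-label cells of each animal. The
deterministic pairing rule makes the statistic reproducible without a
seed.

### Genotype activity fractions

A hypomorphic allele is modelled as an activity fraction f ∈ [0,1]:
the fraction of functional protein produced per unit mRNA relative to
wild type. Defaults: 0.25 for the partial-loss alleles *elt-1(ku491)*
and *ceh-16(bp323)* (heterozygotes behave like wild type, so activity
is below 50% but clearly above zero) and, for the strong-loss allele
*egl-18(ga97)*, 0.0001 in the MRA stage (0.01% activity) versus 0.01
in the ODE stage. The two stage defaults are kept as printed rather
than harmonized, since the analyses were developed with different
conventions; both are overridable (`genotype_activities()`).

## 2. Modular Response Analysis for hypomorphs

For gene *i* and perturbed gene *j*, the central fractional difference
is

R_ij = 2 (x_i(j) f_ij − x_i(0)) / (x_i(j) f_ij + x_i(0)),

with f_ij = γ_i if i = j and 1 otherwise: only the mutated gene's own
transcript must be converted to an effective working-protein level.
R_ij is bounded in (−2, 2). The local response matrix is

r = −(diag(diag(Rp⁻¹)))⁻¹ Rp⁻¹,  i.e. r_ij = −(Rp⁻¹)_ij / (Rp⁻¹)_ii,

whose diagonal is exactly −1 — the normalization encoding first-order
self-degradation; MRA cannot detect other self-loops. Positive r_ij is
read as activation of *i* by *j*, negative as repression; |r| > 1
means amplification, 0 < |r| < 1 attenuation.

`bootstrap_mra()` resamples cells within every gene × genotype group,
recomputes means → Rp → r per iteration (singular resamples are
skipped and counted, not imputed; condition-number cap 1e8), and
reports the elementwise mean matrix, percentile confidence intervals
(2.5/97.5% by default — the convention chosen for "error bars", which
the source analyses leave undefined) and weak-link flags (interval
straddles zero).

## 3. The Hill-ODE model family

Each gene's transcript level g_i follows

dg_i/dt = b_i + Σ_blocks v_block · Π_{terms in block} H(g_reg) − d_i g_i,

where H is the Hill–Langmuir fraction: (g f)^α / (k^α + (g f)^α) for
activation and k^α / (k^α + (g f)^α) for repression. Terms inside one
AND-block are multiplied and share a single maximum rate v; blocks
combine by OR (summation). Degradation rates d are fixed at 1 — the
model describes fixed points only, so all rates are measured in units
of the degradation rate. Hill exponents default to α = 1 (the main
analysis; α = 3 available for cooperativity comparisons, never
fitted).

Parameter sharing: one `b` per gene; one `v` per AND-block; one `k`
per (regulator gene, role), so a gene that both activates and
represses carries two k's — for the late-L1 topology this yields
k1 (ELT-1 activator), k2 (EGL-18 activator), k3 (CEH-16 repressor)
and k3s (CEH-16 self-activator), i.e. 14 free parameters for the
all-OR variant and 10 for the all-AND variant. (The source analyses
mention "up to 11 unknown parameters"; no counting rule we could
derive reproduces that number, and it is not encoded.)

Degenerate inputs: k = 0 in an activation saturates the fraction at 1
for g f > 0 and is defined as 0 at g f = 0 (the limit along g → 0);
k = 0 in a repression gives 0.

`enumerate_logic_variants()` enumerates all set partitions of each
gene's term set (within-block AND, between-block OR); the variant
count is the product of Bell numbers of the per-gene term counts. For
the late-L1 topology (2 + 2 + 3 terms) this gives 2 × 2 × 5 = 20
variants, ordered deterministically with the all-OR model first and
the all-AND model last.

### Steady states

Fixed points are computed by forward integration (matching the
"limit of the ODE simulation" convention), not root finding: a
Cash–Karp embedded Runge–Kutta 4(5) with relative/absolute error
tolerances 1e-9/1e-11 and a step cap of 10 time units, run until
max_i |dg_i/dt| / max(g_i, 1) < 1e-8 or t > 1e4. The integration
tolerances are deliberately tighter than usual because the
steady-state residual criterion must be resolvable; the step cap
avoids stability-boundary bouncing of an explicit method near the
fixed point. States are clamped at zero (production is bounded and
degradation linear, so exact dynamics are non-negative; clamping only
removes numerical undershoot). Non-convergence raises an error
carrying the tail state, or flags the state when `strict = FALSE`
(the sampler treats such proposals as rejections). A root-finding
cross-check appears in the tests via closed-form oracles, not in the
package path.

## 4. Sparse likelihood-free model discovery

Model fit is scored by the normalized Euclidean (ABC) distance

d(S) = sqrt( (1/(n m)) Σ_ij ((μ_ij − s_ij)/σ_ij)² )

over n genes and m genotypes (the square-root "normalized Euclidean"
reading; the double-mutant cutoff 2.5 is interpreted on this scale).
Initial states for every steady-state evaluation are the data means,
which converge quickly.

`sling_fit()` realizes the sparse likelihood-free Gibbs search. The
published sampler's exact mechanics live in a separate methods paper,
so this module is a documented stand-in with the same interface and
the same documented behavior:

* **Kernel.** Component-wise Metropolis-within-Gibbs targeting
  exp(−d/δ) × prior — the minimal realization of "δ scales the
  distance measure in the acceptance probability".
* **Shrinkage hierarchy.** Every parameter has a Laplace slab whose
  scale s_p is resampled each sweep from its inverse-gamma full
  conditional (IG(a+1, b+|θ|) when active, the IG(a, b) hyperprior
  when zero), with a = 2 and b = 0.05 × prior bound — slabs sit on
  the data scale so that birth proposals land at plausible
  magnitudes.
* **Exact zeros.** Removal/reinstatement is a reversible-jump-style
  link move: a block rate v is born together with any half-occupation
  constants its block needs that are not already in use (all drawn
  from their slabs, so slab densities cancel in the acceptance
  ratio), and dies together with constants left orphaned. Constants
  are therefore structurally tied to links: k ≠ 0 exactly when some
  active block uses it. This eliminates degenerate "v with k = 0"
  modes that would mimic basal production, which is why a no-network
  fit retains exactly the three basal rates.
* **Coordinated jumps.** Link birth/death additionally refreshes the
  target gene's basal rate from its spike-and-slab prior and redraws
  the half-occupation constants of downstream links that read the
  target gene (again with cancelling densities): a regulatory term
  substituting for basal synthesis, or invalidating a downstream k,
  is reachable in one move instead of requiring an improbable
  sequence of single-parameter steps.
* **Sparsity strength.** The prior odds of link absence are
  parameterized directly as `link_log_odds` (default 50): a link
  enters or survives only when it improves d by more than
  `link_log_odds × δ`. This gives δ its documented semantics — at
  δ = 0.0125 a link must buy ≈ 0.6 distance units, at δ = 0.1 it must
  buy ≈ 5, which strips the network to basal productions. Basal rates
  use an ordinary spike weight (0.4): baseline synthesis is not the
  hypothesis under test. These constants were calibrated once on the
  `final-L1` synthetic preset so that the δ sweep reproduces the
  method's documented qualitative behavior, then frozen.
* **Burn-in and δ readjustment.** Burn-in runs at the user's δ (a
  small δ makes burn-in an effectively greedy descent) and is
  multi-start: `n_starts` (default 6) independent prior
  initializations are burned in and sampling continues from the best
  endpoint — restarts are the guard against greedy local modes.
  Afterwards δ is re-evaluated: it is kept if (best burn-in
  distance)/δ ≤ 35 and raised to best/35 otherwise, so chains that
  cannot fit the data tightly still mix. In sign-relaxed mode a
  dedicated sign-flip proposal (v → −v) lets chains cross between
  activation and repression readings of a link.
* **Final fit.** The accepted state of minimal distance after
  burn-in. "Kept" means |θ| > 1e-3 × prior bound for b and v, and
  exactly nonzero for k (a small k is functionally meaningful — it is
  compared against g·f, which is below one count for the strong-loss
  mutant — and under the link-tied prior k ≠ 0 ⇔ link active).
  `predict_genotype()` summarizes a run either by this final fit or
  by the elementwise median of post-burn-in states restricted to kept
  parameters ("median parameter set").

Sign-relaxed (a/r) mode gives every block rate full real support; the
sign selects the Hill form at evaluation time (positive = activation,
negative = repression, |v| the rate). For multi-term AND blocks the
selected form applies to every member — exact for singleton blocks,
which is the primary use. The naive baseline (`fit_naive_model()`)
fits the all-activation literature topology by plain random-walk
ABC-MCMC with flat priors (sparsity off).

The move set is adapted (multi-start burn-in, per-class priors), so
post-burn-in samples are best read as an exploration of well-fitting
sparse models rather than an exact posterior sample; all reported
quantities (final fits, presence percentages, predictions) are defined
on that basis.

## 5. Network assembly and validation

`parameter_presence()` reports, per parameter and per link, the
percentage of runs whose final fit retains it; a link counts as
present when any kept block rate realizes it, with the logic context
(AND = multi-term block, OR = singleton) recorded per run.
`filter_by_double_mutant()` scores each run's predicted double-mutant
steady state against held-out double-mutant data with the m = 1 ABC
distance and keeps runs with d ≤ 2.5 (boundary inclusive, per run —
one chain is one unit of validation). `final_network()` deletes links
absent from the final fits of ≥ 90% of kept runs (boundary inclusive)
and annotates survivors with overall and per-logic-context presence.

## 6. The synthetic data generator

`generate_dataset()` emulates the structure of the real data without
reproducing it: for each genotype the ground-truth model's steady
state s_i is computed; each animal draws one extrinsic factor E_a from
a unit-mean log-normal with CV = `extrinsic_cv` (default 0.8), shared
across genes and cells of that animal; each cell count is
Poisson(E_a · s_i). Mutants act only through the activity fractions
inside the steady state, never through the noise parameters. Closed
forms used as oracles: Fano = 1 + cv²·s and paired-cell correlation =
cv²s/(1 + cv²s).

Defaults state the emulated world: 60 animals per genotype with two
measured cells each (about 120 cells per group, matching the scale of
the real measurements), extrinsic CV 0.8 chosen so generated CVs fall
inside the observed 0.6–1.2 band at steady states in the tens of
counts. Presets: `final-L1` (the validated reduced network — elt-1
basal only, egl-18 repressed by CEH-16, ceh-16 activated by ELT-1 OR
EGL-18), `literature` (the naive all-activation network) and
`basal-only`. Only the late-L1 stage is parameterized; other
timepoints are user-configured.

What a green test does **not** establish: the generator has no bursty
transcription, no cell-cycle structure, no cross-gene differences in
extrinsic noise, no animal-level stratification of the bootstrap, and
mutant alleles with exactly the assumed activity fractions. Agreement
on synthetic data shows the pipeline recovers the stated world, not
that the biological conclusions are correct.

## 7. Known limitations

* Bootstrap `sigma` ignores animal-level correlation (see §1).
* The sampler is a documented stand-in for the published
  likelihood-free Gibbs method; presence percentages from the real
  study are not expected to be reproduced numerically.
* The sign-relaxed semantics for mixed AND blocks (sign applies to
  the whole block) is a convention; the source text only needs the
  singleton-block case.
* MRA assumes perturbations act through the measured transcripts with
  the assumed activity fractions; misspecified γ biases the diagonal
  corrections.
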