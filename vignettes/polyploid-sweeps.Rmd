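---
title: "Hard-sweep signals across ploidy levels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-sweep signals across ploidy levels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polysweep simulates and analyses the population-genomic footprint of a hard
selective sweep in autopolyploid populations. Chromosome copy number `k`
enters the model in two distinct ways -- through the population-scaled
mutation and recombination rates (`theta = 2Nk*mu`, `rho = 2Nk*r`) and
through the dynamics of selection (dosage-masked fitness effects slow allele
frequency change, roughly doubling additive fixation times per doubling of
`k`) -- and the package is built to separate those two routes.

## The selection model

An individual carries `k` chromosome copies; a genotype with derived-allele
dosage `d` has fitness `1 + h(d) s`, where `s` is the fitness difference
between the alternative homozygotes and the dominance coefficient is a
power function of the dosage fraction:

    h(d) = (d/k)^tau,   tau = 10^(-H),   -0.5 < H < 0.5.

`H` is the *dominance scalar*: `H = 0` is additive (`h` linear in dosage),
`H < 0` gives `tau > 1` (convex, recessive-like masking of the derived
allele in heterozygotes), `H > 0` gives `tau < 1` (concave, dominant-like).
The printed form of this mapping in the source literature is typographically
ambiguous; `10^(-H)` is the unique simple exponential consistent with all of
its stated properties (continuity, `tau(0) = 1`, recessive means `tau > 1`),
and `selection_model(tau_map = ...)` exposes the mapping as a hook. Dominance
is indexed by *derived* dosage so that the all-derived homozygote has fitness
`1 + s` exactly; indexing by ancestral count, as one reading of the source
would have it, would contradict the definition of `s`.

With random union of gametes (polysomic inheritance, no double reduction,
no selfing, no preferential pairing), genotype dosage at frequency `p` is
`Binomial(k, p)` and one generation of selection gives

    p' = E[ (d/k) (1 + h(d) s) ] / E[ 1 + h(d) s ],

a ratio of binomial expectations (`expected_frequency()`). Drift is one
binomial draw of all `N k` transmitted copies around `p'`
(`wright_fisher_step()`; the sum of `N` independent `Binomial(k, .)`
genotype dosages is exactly `Binomial(Nk, .)`, so a single draw is
distribution-identical and O(1)). A trajectory starts at a single copy,
`p0 = 1/(kN)`, and is iterated to absorption; `simulate_trajectory()`
rejection-samples until a run fixes (default budget `1e6` attempts),
recording the number of losses, which makes fixations/attempts an unbiased
estimator of the fixation probability (about `2s/k` for additive mutations
with `Ns >> 1 >> s`).

## The trajectory-conditioned coalescent

`simulate_sweep_sample()` draws haplotypes backward in time through three
phases:

1. **Post-fixation** (`tau_post` generations, default 0): neutral
   coalescence within each of the two populations, rate `1/(Nk)` per pair
   per generation; recombination at `r` per bp per generation on each
   lineage's ancestral-material hull.
2. **Sweep** (exactly the trajectory's length, in generations, selected
   population only): every lineage carries an allelic class at the selected
   site. With derived frequency `x_t`, derived pairs coalesce at rate
   `1/(x_t N k)`, ancestral pairs at `1/((1-x_t) N k)`; a recombination
   breakpoint between a lineage's material and the selected site moves the
   separated piece to the derived background with probability `x_t`. The
   class sizes are hard-bounded by the available copy numbers
   (`ceiling(x_t k N)`), and at the trajectory's origin all remaining
   derived lineages are coalesced into the single original copy, whose
   ancestor joins the ancestral background. The two populations merge
   (backwards) at that origin -- the split and the mutation are
   simultaneous by construction.
3. **Ancestral population**: a single neutral population until all sampled
   material reaches its local most recent common ancestor.

Events in the sweep phase are drawn generation by generation, exactly on
the trajectory's grid; neutral phases use continuous exponential waiting
times (the standard, faster approximation, exact in distribution for the
rates used). The engine is written in C++ (Rcpp) because the calibration
suites run thousands of ancestral-recombination-graph replicates; it draws
all randomness from R's RNG, so `set.seed()` governs every stage.

Mutations are dropped afterwards (`drop_mutations()`): Poisson with mean
`mu` times the genealogy's total branch area (bp x generations), uniform on
branches and positions, infinite sites. Material whose descendant set is the
whole sample is pruned during simulation, so every emitted column is
segregating. Positions are quantized to `1e-6` fractions of the locus --
the precision of the ms `positions:` line -- with collisions redrawn, so
ms round-trips are bit-exact.

In decomposition experiments the trajectory's ploidy `k_traj` and the
genomic ploidy `k_genomic` are set independently; the sweep phase then uses
the trajectory's length *in generations* unchanged. This is the literal
reading of the model and has a consequence worth knowing: physical escape
of linked material from the sweep depends only on `r` and the trajectory,
so the mixed cell `(k_traj = 4, k_genomic = 2)` has the same escape profile
as `(4, 4)` but a higher relative diversity floor (`T/(Nk)`), and its
measured half-baseline breadth lands *below* both pure cells rather than
between them.

## Statistics

Windows are `L/(N/50)` bp wide with half-width steps (every interior site
falls in exactly two windows): 50 kb at `N = 1000`, 5 kb at `N = 10000`.
Per window the package reports per-site pairwise diversity, Tajima's D
multiplied by -1 (so the post-sweep excess of rare variants scores
positive), and Hudson's `F_ST = 1 - pi_within/pi_between` as a ratio of
window sums. The F_ST estimator uses plug-in allele frequencies (within:
mean of `2p(1-p)`; between: `pA(1-pB) + pB(1-pA)`): with that form two
identical samples give exactly 0 and fixed differences exactly 1, the
contracts the toy tests pin down. `mean_standardize()` centres and scales
F_ST across windows within a replicate. Tajima's D uses the haplotype count
`n*k` as its sample size -- ploidy enters the statistics only through the
number of sequences sampled.

Haplotype statistics follow the cited conventions: EHH is the probability
that two random carriers of the focal allele are identical over the
intervening interval (1 at the focal site, non-increasing outward); iHH is
its trapezoidal integral in bp, truncated where EHH drops below 0.05; iHS
is `ln(iHH_ancestral/iHH_derived)`, standardized in 50 equal derived-
frequency bins pooled across replicates (per-replicate site counts are too
small to bin); XP-EHH is the population-wide log-ratio
`ln(iHH_selected/iHH_neutral)`, standardized within replicate. Focal sites
for iHS require minor-allele frequency 0.05. Undefined values (zero iHH,
`S = 0` windows, zero between-population diversity) propagate as `NA`,
never as zero.

## Peak summaries

Diversity profiles are LOESS-smoothed (degree 2, tricube weights, no
robustness iterations, span 0.1 by default; the effective span is floored
at 5 points per local fit so that coarse-window profiles remain
identifiable, and the fit skips its standard-error bookkeeping, which is
numerically fragile at small spans). The baseline is the mean of the
non-selected population's smoothed profile (median available via
`baseline_stat`); the aggregation is a package choice, as the source states
none. `Magnitude` is baseline minus profile minimum; `Breadth` is the
distance between the first positions left and right of the selected site
where the profile recovers to *half the baseline* (the alternative
half-depth reading is not used), divided by 100 kb; `Area` is exactly
`Magnitude * Breadth / 2`. Profiles that never dip below half baseline get
breadth 0 and a `no_dip` flag; profiles that never recover within the locus
are `censored` at the profile edge. For other metrics the summary is the
signed maximum and the trapezoidal area under the profile within 100 kb of
the selected site, divided by 100 000. `cv_bootstrap()` reports the
coefficient of variation of per-replicate maxima with a
200-out-of-n, 1000-iteration bootstrap interval, and `persistence_curve()`
tracks medians of maxima and area quartiles across sampling delays.

## The experiment driver as synthetic-data generator

`run_experiment()` is also the package's test-data generator. Its defaults
state the simulated world: two populations of `N` individuals splitting at
the moment the beneficial mutation arises mid-locus on 1 Mb, `n = 10`
individuals (`n*k` haplotypes) sampled per population at fixation,
`mu = r = 1e-8` per bp per generation (the headline study states its exact
values only in supplementary material unavailable here; `1e-8` is the
textbook eukaryote-scale rate and makes `theta = 2Nk*mu` span realistic
per-site diversities of `4e-5`-`8e-4` across the grid). The headline grid
(`default_paper_grid()`) crosses `k in {2,4,8}`, `s in {0.001,0.01,0.1}`,
`H in {-0.4,0,0.4}`, `N in {1000,10000}`, with a desk-scale replicate
count. Per-replicate seeds are `master + 100003*cell + 101*rep` (mod
`2^31 - 1`), so any replicate can be regenerated in isolation and identical
configs give byte-identical TSVs. Failed replicates (e.g. rejection-budget
exhaustion for recessive mutations at high ploidy) are logged and skipped;
a fully failed cell aborts.

What the generator does *not* emulate: demographic change, migration after
the split, selfing or double reduction, gene conversion or interference,
recurrent or standing variation (hard sweeps only), unphased or missing
data. A green calibration therefore establishes internal consistency of
the model's own world, not robustness to those forces.

## Numerical choices

- Frequencies are exact lattice multiples of `1/(kN)`; absorption tests are
  exact comparisons with 0 and 1, not tolerances.
- Stochastic trajectories have no generation cap (absorption is certain);
  the deterministic path has an explicit cap since with `s = 0` it would
  never terminate.
- Sweep-phase multi-events: within one generation, pair-coalescence draws
  are repeated after each merger, allowing several mergers per generation;
  per-pair probabilities >= 1 merge deterministically.
- The recombinable span during the sweep extends from the material hull to
  the selected site (class-changing recombination needs the selected-site
  side); in neutral phases it is the hull alone, where breakpoints outside
  material would be invisible.
- `area_under_peak()` interpolates the profile linearly at the interval
  endpoints before integrating, and is checked against a fine-grid Riemann
  oracle at `1e-6`.

## Known limitations

- iHS/XP-EHH are O(sites x haplotypes) per focal site in R; they are
  computed on demand (`haplotype_stats = TRUE`), not in the default
  experiment path.
- The structured coalescent treats the unselected population as completely
  isolated after the split; no migration option is provided.
- Sample sizes are per population and constant; the by-allele sampling mode
  changes only the haplotype count, not the individual grouping semantics.
- `read_ms()` accepts only this package's dialect (header comment with
  population sizes); arbitrary ms output from other tools may lack the
  header and is rejected rather than guessed at.
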