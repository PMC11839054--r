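---
title: "cladecall: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cladecall: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what the model
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. From genomes to a clade database

**Inputs.** Per-position stranded nucleotide counts for a collection of
same-species reference genomes aligned to one assembly (produced
externally by an aligner and pileup; `cladecall` consumes the documented
TSV format or plain mpileup text), and a rooted phylogeny of those genomes
with bootstrap support. Coordinates are 1-based inclusive throughout,
matching pileup convention, and are enforced at every reader boundary.

**Base calling.** The call at each (genome, position) is the major allele
unless an ambiguity rule fires, in which case it is `N`. The rules are
evaluated independently and OR-combined (order-free, which the tests
verify): consensus quality above −30 on the pileup caller's scale (more
negative = more confident; the native format stores a generic
`call_quality` defaulting to a sentinel that never fires, decoupling the
model from one pileup dialect), major-allele depth below 3 on either
strand, major allele frequency below 0.85, or more than a third of reads
supporting an indel within 3 bp. "33%" is implemented as the exact
fraction 1/3 with a strict inequality. The strand rule is applied to
major-allele reads (not all reads on the strand) — the stricter and, we
judged, intended reading; "median coverage" sums both strands.

**Filters.** Genomes with median depth < 8X are dropped; positions where
> 10% of remaining genomes are `N`, median cross-genome depth < 5X, or
median depth exceeds twice the overall per-position-median (a copy-number
proxy) are dropped; genomes with > 10% `N` among the *surviving* positions
are then dropped (the printed order — the second genome filter depends on
the retained positions). The in-clade ambiguity rule for barcodes uses a
strict `< 10%` reading. Filtering is idempotent and monotone in its
thresholds; both are property-tested.

**Tree scaling.** Branch lengths are rescaled into SNV units by the
least-squares through-origin slope of patristic distance against pairwise
Hamming distance (ambiguous positions skipped pairwise), provided their
Pearson correlation exceeds 0.75. The origin is forced because zero
evolutionary distance must map to zero SNVs. An unscalable tree is kept in
raw units and every criterion expressed in SNVs refuses to run unless
explicitly overridden — silently applying a "1000 SNV" cutoff to
arbitrary units would be worse than failing.

**Clades and barcodes.** Every internal node (except the two root-adjacent
branches, whose split is a rooting artefact — unrooted input trees are
midpoint-rooted) is a candidate clade; it is accepted with ≥ 4 members, a
subtending branch ≥ 1000 SNVs, and bootstrap strictly > 0.75. Its barcode
is the set of (position, allele) pairs unanimous among non-`N` members,
ambiguous in < 10% of members, carried by **no** genome outside the clade
(all non-members, the strictest reading of "not found in any other
clades"), and — when outgroup genomes are supplied to absorb cross-taxon
read recruitment — callable in ≤ 10% of outgroups. Clades with fewer than
10 barcode SNVs are removed. Because nested clades draw their barcodes
from different branches, a clade's barcode is provably disjoint from its
ancestors' (tested). "Branch length" of a clade always means the single
branch subtending its MRCA — the branch whose mutations *are* the barcode.

**Hierarchy levels.** Accepted clades are layered by nesting depth
(level 1 = outermost). Clades at one level are disjoint by construction,
which is what makes per-level abundance normalization meaningful.

**Dereplication.** Near-identical genomes can be collapsed before database
construction with density clustering (DBSCAN, ε = 500 SNVs, core size 2)
on the Hamming matrix, keeping the highest-median-coverage genome per
cluster (ties broken lexicographically for determinism) plus all
singletons.

## 2. The two-step zero-inflated model

Let x_i be reads supporting clade b's allele at informative position i and
y_i all reads there. Step one fits y as negative binomial
(λ_all, α_all) and builds the dispersion prior α ~ Gamma(a, b = 1) with
a = ȳ/(s²_y − ȳ), as printed in the source method. Two notes:

* The classical method-of-moments shape is ȳ²/(s²_y − ȳ); the printed
  formula differs by a factor of ȳ. We implement the printed formula
  verbatim and expose `classical_shape = TRUE` as a switch.
* When depths are underdispersed (s² ≤ ȳ) the formula is undefined; a
  wide Gamma(2, 0.02) prior (mean 100 — i.e. "essentially Poisson is
  allowed") is substituted and flagged in the output.

Step two models x_i ~ Poisson(λ_i z_i), z_i ~ Bernoulli(1 − π),
λ_i ~ Gamma(α, β). The latent Gamma layer is parameterized with β = α/λ so
the marginal of x_i given z_i = 1 is NB with mean λ and variance
λ + λ²/α — "expected depth" and "excess dispersion" fix this intent, so β
is derived, not free. π is the fraction of barcode positions
*systematically* empty: the metagenomic estimator of the strain's
divergence DV_b from the branch.

**Sampler.** A slice-within-Gibbs scheme (our reconstruction; the original
supplement was unavailable, so the implementation is validated by
parameter recovery rather than draw-level equivalence): exact Bernoulli
updates for z_i with λ_i marginalized through the NB likelihood; conjugate
Beta(1, 1) update for π; stepping-out slice sampling (Neal 2003) on
log λ and log α, the latter under the step-one Gamma prior. Chains default
to 10,000 steps with 10% burn-in and are bit-reproducible given a seed;
a split-R̂ on π above 1.1 is recorded as a convergence warning. Positions
with y_i = 0 stay in the likelihood — zero coverage of *all* alleles is
ordinary depth variation, which the model handles, not evidence of
divergence.

**Prior on λ.** Beyond the source method's stated components we place a
diffuse lognormal prior on λ, centred at λ_all with sdlog 2. This was
forced by a real degeneracy: with a flat log-scale prior, all-zero x is
explained equally well by π → 1 (clade absent) and by λ → 0 with every
z_i = 1 (clade "present" at vanishing depth), and the posterior is
improper. The prior contributes about half a log-likelihood unit against
hundreds of data terms whenever any supporting reads exist (the recovery
tests bound its influence), but it resolves the no-data limit the sensible
way: absent all markers at 50X overall depth, π concentrates above 0.95.
We read this as one concrete form of the stated idea that step one
"constrains possible values of π and λ".

**Fast path.** `fit_zinb_mle()` maximizes the same posterior (prior terms
as penalties) and derives the detection quantities from the normalized
profile likelihood of π over a 51-point grid, its interval standing in for
the HPD. One subtlety mattered: the α penalty must be the *log-scale*
prior density (Jacobian included, as the sampler parameterizes it). With
the natural-scale Gamma density and prior shape a < 1 — which the printed
formula readily produces — the penalty diverges at α = 0 and drags fits
into "infinite overdispersion explains every zero", collapsing π̂ to 0.
This was caught by the prior-value property test and is why that test
exists.

**Inference gate.** A clade is only fit when more than 10 positions carry
at least one supporting read; otherwise it is reported `no_call`. The
all-absent analytic limit is still exercised in tests by overriding the
gate.

**Detection and abundance.** Detected ⇔ (π-mass below 0.35) ≥ 0.5 ∧ (95%
HPD lower bound) < 0.1 ∧ abundance ≥ 1%. The source text contradicts
itself on the direction of the 1% rule in one sentence; the benchmark
reading (≥ 1% detected) is implemented. Abundance is MAP λ_cs / MAP λ_all,
computed per clade independently; a level summing above 1 (sampling noise)
is scaled down to exactly 1, a level summing below 1 is left alone — the
shortfall is the estimated novel fraction at that resolution.

## 3. The synthetic world

`simulate_genomes()` draws a random rooted topology, branch lengths in
expected SNVs, Poisson mutation counts per branch, and places mutations at
globally distinct sites of a 100 kb core, propagating root → leaves.
Defaults are the stated world of the package's benchmarks: 30 genomes,
internal branches Exp(mean 1000) SNVs, terminal branches Exp(mean 300) —
deep, phylogroup-like structure in which a handful of clades meet the
1000-SNV criterion, as in the cutaneous and enteric species the method was
built for. Realized mutation counts become the branch lengths, so
patristic distance equals Hamming distance exactly and scaling recovers
slope 1 — deliberate: unit errors would otherwise be invisible. Mutation
densities above half the core trigger an error instructing a longer core
(distinct-site sampling needs head room; this cap, with the branch means,
is why the internal mean is 1000 and not larger).

`simulate_sample_counts()` emits per-position allele counts, not reads: NB
depth noise per genome (shape 5 by default — moderately overdispersed, so
step one has something real to estimate; ∞ gives Poisson), per-read
substitution errors at a stated rate (default 0 — the original benchmark
reads were simulated error-free), binomial strand splits, and a
lognormal(µ = 1, σ = 1) mixture helper. What this world does **not**
emulate: alignment and mapping errors, cross-species read mismapping from
background taxa, reference bias, recombination, contamination, or
duplicate reads. A green benchmark here certifies the statistical
machinery — barcodes, the ZINB estimator, detection calibration — not
robustness to those artefacts; accordingly our precision/recall sit at the
ceiling of the published values rather than matching them digit-for-digit.

**Hold-out harness.** For every well-supported branch (bootstrap > 0.75,
root-adjacent branches excluded to avoid midpoint-rooting artefacts), all
descendant genomes are removed, the database rebuilt, and one held-out
genome simulated and classified at each coverage. Truth is
DV_b = 1 − shared/total branch length, computed on the *full* tree in the
same SNV units as the database; after pruning, a clade's defining branch
is generally a concatenation of full-tree edges, and the held-out genome's
attachment node splits it into shared and unshared parts. Records whose
inference was declined by the support gate (fully novel lineages) carry no
π̂ and are excluded from correlation summaries — the method's honest
output for them is "nothing", not a number.

**Metrics.** Presence = clade frequency > 1% on both sides;
precision = 1 when nothing is called (no false claims), recall = 1 when
nothing is truly present; F1 = 0 when both are 0. Excess distance weights
each reported genome's extra SNV distance beyond the truly closest
database genome by its reported abundance (weights renormalized to 1 if
needed); an empty output is a distinct no-call, `NA`, not zero.

## 4. Numerical choices and degenerate inputs

* Slice sampling is hard-bounded to |log parameter| ≤ 20; flat
  conditionals (e.g. λ when no position has z = 1) cannot drift into
  under/overflow.
* MAP values are kernel-density modes of the draws (π on [0, 1] support);
  HPD intervals use the sorted-window method and require ≥ 100 draws.
* The MLE multi-starts from π ∈ {0.05, 0.5, 0.95} and falls back to a
  coarse grid (flagged) on optimizer failure; a single unique depth value
  still returns finite estimates.
* Ties in base calling (equal major-allele counts) resolve to the
  alphabetically first nucleotide — irrelevant once the 0.85 frequency
  rule applies, but deterministic.
* All-zero samples classify to `no_coverage` rows with nothing detected,
  and an empty profile normalizes to an empty profile.

## 5. Known limitations

* One π per branch: a known clade and a closely related novel strain in
  the same sample are not deconvolved; the more abundant signal wins.
* π approximates DV_b in mutation units; for highly recombinant species
  the mapping to evolutionary time is loose.
* Single species per run; background taxa enter only as (optional) count
  noise, and their mismapping behaviour is not modelled.
* The candidate-clade flags `-n`/`-p` of the original tool are mapped to
  the in-clade ambiguity and outgroup-callable fractions (both 10%); this
  mapping is an assumption recorded as such.
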