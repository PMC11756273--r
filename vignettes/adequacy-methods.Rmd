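---
title: "Parametric-bootstrap adequacy testing for site-heterogeneous amino-acid models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric-bootstrap adequacy testing for site-heterogeneous amino-acid models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the substitution models, the diversity statistic and its
bootstrap calibration, the PMSF construction, the curation filters, and the
numerical and design decisions a maintainer would want spelled out.

## Substitution models

All models are continuous-time reversible Markov chains on the 20 canonical
amino acids (fixed alphabetical order throughout the package).  A model is
assembled from three parts:

* an **exchangeability matrix** `s` — symmetric, zero diagonal.  Presets:
  *Poisson* (all off-diagonal entries equal) and *LG* (the empirical
  Le–Gascuel matrix, read at run time from phangorn's shipped copy and
  reordered to the package's state order).  Arbitrary symmetric matrices
  are accepted for GTR-style use.
* one or more **frequency profiles** `pi` — 20 non-negative entries summing
  to one.  Profiles are the carrier of across-site compositional
  heterogeneity.
* a **discrete gamma** model of across-site rate variation: `K`
  equiprobable categories (default 4), category rates equal to the exact
  conditional means within quantile bins of a mean-one gamma with shape
  `alpha` (both shape and rate set to `alpha`).  Means, not medians, are
  used, matching the dominant ML-software convention; the weighted mean
  rate is exactly one, so branch lengths stay in expected substitutions
  per site.  `alpha` is a free, user-supplied parameter everywhere
  (default 1): the package performs no ML optimisation of it.

The rate matrix is the standard reversible construction
`Q[i,j] = s[i,j] * pi[j]`, diagonal set so rows sum to zero, scaled so that
`-sum(pi * diag(Q)) = 1`.  Transition probabilities use the symmetrized
eigendecomposition (`D Q D^-1` with `D = diag(sqrt(pi))` is symmetric),
which is numerically stable for reversible chains; tiny negative entries
from round-off are clipped and rows renormalized.

Three model *flavours* share this core:

* **homogeneous** — one profile for every site (e.g. `LG+G4`);
* **mixture** — `k` class profiles with prior weights, shared
  exchangeabilities and gamma (the CXX shape);
* **site-profile** — one profile per alignment site (the PMSF shape); the
  profile count fixes the alignment length.

With Poisson exchangeabilities the rate matrix is of Felsenstein-81 type
and `P(t) = exp(-b r t) I + (1 - exp(-b r t)) 1 pi'` with
`b = 1/(1 - sum(pi^2))`.  Both the simulator and the pruning algorithm use
this closed form when they can — it is what makes 2,000-site, 100-taxon
site-profile simulation cheap — and fall back on the eigendecomposition
kernel for other exchangeabilities.

**Profile regularization.**  A zero profile entry makes the chain
non-ergodic (and a site observing that residue would have likelihood
zero), so `frequency_profile()` floors (near-)zero entries at
`1e-10` and renormalizes by default.  Construction of a rate matrix from
an unregularized profile with a zero entry is an error, not a silent fix.

## The div statistic and the bootstrap

`div` is the mean, over alignment columns, of the number of *distinct*
canonical amino acids observed in the column.  Decisions fixed here:

* gaps (`-`, `?`) and ambiguity codes (`X B Z J * .`) are "unobserved" and
  never count as residues — the statistic counts realized amino acids;
* columns with no observed residue carry no compositional information and
  are excluded from the mean (an all-gap alignment is an error);
* consequently `div` lies in `[1, 20]` and is invariant to row and column
  order.

The adequacy test simulates `n_reps` (default 100) replicate alignments of
the observed alignment's dimensions under the candidate model on the fixed
tree, computes div for each, and reports

```
Z = (mean(div_sim) - div_obs) / sd(div_sim)
```

with the *sample* SD (n−1) — the convention for standard deviates; the
choice matters little at 100 replicates but is fixed for reproducibility.
The sign convention deserves a note: the package reports the *negative* of
the usual standardisation, so that a model which underestimates the data's
compositional heterogeneity — i.e. simulates columns that are too diverse,
the characteristic failure of homogeneous models — receives a large
*positive* Z.  Verbal glosses of this convention in the adequacy
literature are easy to read either way; the implementation pins the
operational definition (simulated mean above observed ⇒ positive Z), which
matches the sign pattern such tests report in practice: homogeneous models
strongly positive, overfitted site-specific models slightly negative.  A
`sign = "standard"` flag gives the plain standardisation; flipping the
flag negates Z exactly.

The verdict is `adequate` iff `-2 < Z < 2`.  That reading presumes the
replicate distribution is roughly normal, which is why every result object
retains the full replicate vector and `autoplot()` draws the histogram
with the observed value marked: Z-scores should be interpreted together
with the distribution, not instead of it.

**Gap handling.**  div is sensitive to per-column sample size: a column
with half its rows gapped can display fewer distinct residues.  Real
matrices are gappy, so by default (`gap_mode = "copy"`) every replicate
gets the observed alignment's exact gap-and-ambiguity mask copied onto it
before div is computed, making observed and simulated values commensurate.
Whether published bootstrap pipelines copy the real missingness pattern is
usually unstated; both behaviours are exposed (`gap_mode = "none"`
simulates complete matrices) and the choice is recorded in every report.

**Replicate seeding.**  Each replicate uses a master seed derived from the
test's seed by an integer congruential hash; each *site* within a
simulation uses its own substream derived from the master seed and the
site index.  This makes batch simulation bit-identical to simulating sites
one at a time and concatenating — the natural scheme for site-profile
models, where each site has its own process — and makes every output
reproducible from `(tree, model, n_sites, seed)` alone.  Within a site,
the random layout is fixed (class draw where applicable, gamma category,
root state, then two uniforms per edge in preorder for the closed-form
kernel, one for the eigendecomposition kernel), so the draw count never
depends on realized states.

## Likelihoods and the PMSF step

Site likelihoods use Felsenstein pruning with per-node rescaling: after
each partial-likelihood combination the column maximum is divided out and
accumulated in log space, so 100-taxon, 20-state products cannot
underflow.  Gap and ambiguous tips contribute a flat partial likelihood of
one over all states; an all-gap column therefore has log-likelihood zero.
Mixtures average over classes with their weights and over gamma categories
with weight `1/K`.  Root placement is immaterial for reversible models
(the pulley principle; verified numerically in the tests), so unrooted
trees are processed from their stored basal node.

The PMSF computation takes a fitted mixture and a fixed tree and produces
one profile per site: the class posterior at site `i` is

```
p_k(i)  ∝  w_k * (1/K) * sum_c L(site i | class k, category c)
```

— gamma categories are marginalised *inside* each class, giving the
posterior over classes with rates summed out — and the site's profile is
the posterior-weighted average `sum_k p_k(i) pi_k`.  The output model
reuses the mixture's exchangeabilities and gamma, and is by construction a
convex combination of the class profiles (asserted to 1e-9 in the tests).
A site with zero likelihood under every class is an error; it cannot occur
once class profiles are regularized.

Two file dialects are supported for per-site profiles: the IQ-TREE
site-frequency layout (one line per site: index + 20 frequencies; one
profile set per file) and a Phylobayes-style block layout (amino-acid
header line, then one block of per-site rows per posterior sample, site
indices restarting at each block).  The Phylobayes-style reader is pinned
to the fixture format shipped in this repository, since the upstream
format is not standardised in print; rows are renormalized on input to
absorb file rounding.  When several posterior samples are read, the
exported per-site profile is their arithmetic mean, renormalized —
averaging is the documented default for turning posterior samples into a
single site-frequency file, and the samples are kept available for any
other treatment.

## Curation filters

Gene families (alignment + gene tree + sequence-to-taxon map) pass through
three filters, applied in the documented order gap/length → paralogue
resolution → long-branch removal.  The ordering between paralogue
resolution and long-branch removal is a package decision — sources of such
pipelines rarely pin it down — and each filter is a no-op on an
already-excluded family, so the order is easy to change downstream.

* **Gap/length**: sequences with more than 25% unobserved characters are
  removed; families whose alignments do not keep strictly more than 50
  columns (or at least 2 sequences) are excluded.  The strict inequality
  at 50 follows the `-m 50` convention of the filtering tools this
  operator mirrors.
* **Long branches**: per pass, the mean and sample SD of the current gene
  tree's branch lengths are computed and every *leaf* whose terminal
  branch exceeds `mean + 2 SD` is removed; the tree is pruned (not
  re-inferred) and the pass repeated, twice by default.  Iteration is the
  point: one extreme branch inflates the SD enough to shield lesser
  outliers that only the second pass catches (demonstrated in the test
  suite with a constructed 50/3/0.1 example).  The mean/SD pool is all
  branches (internal + terminal) by default — "the branch-length
  distribution of the family tree" is the natural reading — with
  `pool = "terminal"` available, and removal only ever applies to leaves
  via their terminal branches.  A pass that would leave fewer than 4
  leaves is skipped and flagged rather than executed.
* **Paralogues**: for each taxon owning several sequences, monophyly of
  the copies is evaluated in the *unrooted* sense (the set forms one side
  of some bipartition) because gene trees carry no meaningful root; ties
  in the "shortest terminal branch" rule resolve to the first-listed copy.
  Any non-monophyletic multi-copy taxon excludes the whole family.

Every removal is logged (sequence, reason, pass), the log replays exactly
(`replay_curation_log()`), and excluded families keep their data for
audit.

## The synthetic-data generators

The fixture generators define the package's study conditions:

* **Trees**: balanced/pectinate/star shapes with i.i.d. uniform(0.05, 0.5)
  or exponential(rate 5) branch lengths, and random coalescent genealogies
  (`ape::rcoal`) whose own branch lengths are kept.  The calibration and
  discrimination studies use 100-taxon coalescent trees: many short
  internal branches and tip branches of realistic heterogeneity, the shape
  regime where compositional misfit matters in practice.
* **Site profiles**: symmetric Dirichlet draws.  Concentration 0.5 gives
  moderately heterogeneous profiles; 0.1 gives sparse profiles in which a
  handful of amino acids carry nearly all mass — the CAT-like regime
  (under the fixed seed protocol the mean number of entries above 0.05 is
  below 6 of 20).  A `k_class` variant draws `k` class profiles and
  assigns sites uniformly, emulating finite mixtures.
* Eight synthetic hypothesis topologies for ecdysozoan relationships ship
  as Newick fixtures so that "profile estimated under topology X"
  experiment shapes can be exercised; they are constructed stand-ins with
  invented branch lengths, not published trees.

What these fixtures do *not* emulate: indels and alignment error
(missingness enters only by copying observed masks), among-branch
compositional drift (profiles are constant along the tree), selection of
profiles by any empirical mixture (classes are Dirichlet draws, not C60),
and the scale of real supermatrices.  Passing the package's checks
therefore shows the *machinery* is correct and calibrated under its own
generating assumptions — it does not certify any particular empirical
model as adequate for real data.

## Study sizes and calibration

The two headline self-checks (also recomputed by `scripts/acceptance.R`)
run ten independent trials of: a 100-taxon coalescent tree, 2,000
Dirichlet site profiles, Poisson exchangeabilities, gamma shape 1 with 4
categories, one simulated "observed" alignment, and a 100-replicate
adequacy test.

* *Self-consistency* (concentration 0.5, tested under the generating
  model): under the true model the observed div is one more draw from the
  replicate distribution, so Z is approximately a standard normal deviate
  and |Z| ≤ 2 should hold in the large majority of trials; the check
  requires 9 of 10.  The 2,000-site scale keeps the Monte-Carlo error of
  div small without being expensive (a trial runs in seconds).
* *Discrimination* (concentration 0.1, tested under the homogeneous
  mean-profile model): averaging sparse site profiles into one shared
  vector makes simulated columns far more diverse than observed ones, so
  Z is large and positive; the check requires Z > 2 in 9 of 10 trials.

A smaller-scale calibration property (20 trials at 16 taxa × 250 sites,
40 replicates) additionally bounds the fraction of |Z| > 2 at 0.25 — the
statistic need not be exactly standard normal, and the bound is
deliberately loose.  A three-model ordering study (homogeneous mean <
15-cluster mixture approximation < generating site-profile model, on
sparse-profile data) checks that Z-scores rank model resolution correctly
in at least 4 of 5 seeds.

## Numerical choices, degenerate inputs, limitations

* Tolerances: profile sums to 1 within 1e-9; rate-matrix row sums,
  normalization and detailed balance within 1e-9; transition-matrix
  stochasticity within 1e-9 (clipped negatives re-normalized); pruning
  vs. exhaustive enumeration within 1e-9; gamma rates vs. quadrature
  within 1e-6; file round-trips within 1e-12.
* Degenerate inputs rejected with messages rather than propagated: trees
  without (or with negative/missing) branch lengths name the offending
  edge; adequacy with fewer than 2 replicates; zero replicate SD; all-gap
  alignments for div; malformed profile rows name their line.
* `n_reps = 100` default mirrors the standard bootstrap size for this
  test; seeds are plain integers and every derived seed stays below 2^31.
* Known limitations: no indel simulation; no among-branch compositional
  drift; no ML optimisation of alpha, branch lengths or topology (the
  tree is always user- or fixture-supplied); only div ships as the
  adequacy statistic, though the result object is built so further
  statistics could be added; the AU topology test itself is out of scope —
  only its repeated-testing Bonferroni arithmetic
  (`bonferroni_alpha(0.05, 8) = 0.00625`) is provided for harnesses that
  run one test per candidate profile.
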