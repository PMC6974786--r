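---
title: "Analog-series-based activity cliffs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog-series-based activity cliffs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the model behind `accliff`, the parameters that
matter, the numerical conventions chosen where several were defensible, and
what the synthetic study conditions do and do not demonstrate.

## The method

### Compounds and target sets

Input records are (compound, SMILES, target, pKi). Potency must be an
assay-independent equilibrium constant on the pKi scale (one unit = 10-fold
in Ki); Ki in nM is converted as pKi = 9 − log10(Ki). Structures are
salt-stripped (largest carbon-containing component by heavy atoms) and
canonicalized with OpenBabel; records with the same canonical structure and
target are one compound, replicate potencies aggregated by the arithmetic
mean (median and a discard-if-range-exceeds policy are available — the
method itself does not prescribe an aggregation rule, and the mean is the
least surprising default). Stereochemistry is retained at this stage: two
stereoisomers are distinct compounds. A *target set* is all curated
compounds of one target; sets need at least two compounds, and any
downstream statistic needs at least two analog pairs.

### Fragmentation and analog series

Every exocyclic (acyclic) single bond between heavy atoms that matches a
retrosynthetic RECAP bond type is cleavable. The rule catalog — urea,
amide, ester, sulfonamide, quaternary nitrogen, lactam N–aliphatic C,
aromatic N–aliphatic C, amine, ether, biaryl, olefin — is ordinary data
(`recap_rules()`): each rule is a predicate over a bond's environment, list
order is precedence (specific environments first, so an amide C–N is never
labeled "amine"), and users can edit the list. The classical olefin cut
cleaves a C=C double bond and is therefore inert under the
exocyclic-single-bond regime; it stays in the catalog for completeness.

For each compound, every subset of cleavable bonds of size 1–5 is cut
simultaneously. A subset is a valid split only if exactly one resulting
fragment — the core — is incident to every cut bond (star topology; subsets
that chop one substituent into two pieces are discarded), and the core must
have at least twice the combined heavy-atom count of the substituents (the
comparison is non-strict, "at least twice"). Open valences on the core
become implicit hydrogens when it is canonicalized, which *is* the
hydrogen-generalized core representation. Enumeration is capped at 5,000
bond subsets per compound (configurable); beyond it the compound is skipped
and logged rather than stalling the run.

Compounds sharing a generalized core form an analog series. Two
representation choices deserve explanation:

* **Series identity is the marked core.** Grouping by (core SMILES, site
  count) alone would merge series whose sites sit at *different positions*
  of the same core (meta- vs para-substitution), which breaks substituent
  tuples. Series are therefore keyed by the canonical SMILES of the core
  with all sites marked by dummy atoms, a strict refinement that keeps
  tuples well defined.

* **Site correspondence by orbit descriptors.** To compare members slot by
  slot, each site carries a descriptor: the canonical SMILES of the core
  with that one site marked. Slots are ordered by descriptor; within runs
  of equal descriptors (symmetry-equivalent sites) substituents are
  compared as multisets. Symmetric sites therefore never produce spurious
  differences; in the rare case of a core whose automorphism group cannot
  realize a needed site exchange (reflection-free symmetric cores), the
  reported differing-site count is an upper bound, and structurally
  distinct members whose tuples collide are floored at one differing site.

A member whose core position is unsubstituted participates with a hydrogen
sentinel at that slot: a compound whose split has the same core but fewer
sites (or which *is* the bare core) is enrolled when marking additional
free-valence core atoms reproduces the series' marked-core key. This makes
H→R pairs first-class analog pairs.

### Threshold and cliffs

All analog pairs of a target set are pooled. The same unordered compound
pair often appears through several cores; by default it is counted once,
keeping the representation with the fewest differing sites (ties: larger
core). Without deduplication the delta distribution would double-count
structural pairs; both behaviours are available (`dedup` flag) since the
method description leaves the distribution's support ambiguous.

The set-specific cliff criterion is mean + 2·sd of the pair delta-pKi
distribution. The standard deviation is the sample (n−1) estimator by
default (`sigma_mode = "population"` is available; the method text says
only "sigma"). The comparison Δ ≥ threshold is non-strict: an inclusive
boundary avoids floating-point fragility at exact equality. Before any of
this, target sets pass the pre-selection gate IQR ≥ 1, also non-strict.
Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7, the default convention; configurable). Note the
interpolating conventions disagree on small samples — three points give an
IQR of 0.4 under type 7 but 0.8 under type 6 — which is why the convention
is pinned and exposed.

### Dual-site decomposition

For a cliff differing at two sites, the two hybrids (weaker compound with
one substitution swapped to the stronger compound's substituent) are
assembled by grafting the substituent graph onto the recorded core atoms,
canonicalized, and looked up in the target set. With both hybrid shifts d1,
d2 and the cliff difference D:

* *determined_by_one* if max(d1,d2) ≥ 0.8·D and min(d1,d2) < 0.2·D;
* otherwise *both_contribute*, with effect *additive* when |d1+d2−D| ≤ 0.5,
  *synergistic* when d1+d2 < D−0.5, *compensatory* when a shift is negative
  while D > 0 or when d1+d2 > D+0.5.

The dominance fraction (0.8) and tolerance (0.5 pKi) are explicit,
documented parameters rather than hidden constants, because the literature
on these classifications does not print numeric cutoffs; 0.5 pKi is a
common estimate of inter-assay reproducibility, and 0.8 dominance mirrors
the 95%/5% split used in the dominant-substitution test preset. With only
one hybrid found the pattern is reported *unclassified* — a single shift
cannot distinguish dominance from synergy. Only dual-site cliffs are
decomposed; cliffs with 3–5 differing sites are reported but not further
analyzed.

## Parameters at a glance

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `min_iqr` | 1 | pKi | potency-spread gate for target sets |
| `max_sites` | 5 | sites | maximum simultaneous cut sites |
| core size rule | ≥ 2× | heavy atoms | core vs combined substituents |
| `max_subsets` | 5000 | subsets | combinatorial cap per compound |
| `sigma_mode` | sample | — | sd estimator for the threshold |
| `quartile_type` | 7 | — | quartile interpolation convention |
| `dedup` | TRUE | — | one count per structural pair |
| `dominance_fraction` | 0.8 | — | "determined by one" cutoff |
| `tolerance` | 0.5 | pKi | additivity tolerance |
| MMP limits | 13 / 8 | heavy atoms | max substituent / max exchange difference |

## The synthetic study conditions

The generator (`fixture_spec()`, `generate_fixture()`) builds small
ether-linked analog series on asymmetric dihydroxy-arene scaffolds
(fluoro-, pyridine- and methyl-variants, so cores are pairwise disjoint and
no spurious cross-series analogs exist). Substituents attach through ether
oxygens, hence through RECAP-cleavable bonds, and potency is exactly
additive: baseline + per-substituent increments + Gaussian noise.

The standard preset encodes the conditions under which the method's
behaviour is provable:

* `T-PLANT` (28 compounds, noise sd 0.05): three series with staggered
  baselines 5.0/6.5/8.0, so the *compound* IQR (≈2.9) is driven by
  between-series offsets while within-series pair deltas stay ≤ 0.35 —
  pair-delta spread and compound spread are decoupled, which is the only
  way a set can simultaneously pass IQR ≥ 1 and keep distractor pairs far
  below the threshold. One planted analog (+5.0) creates 9 pairs whose
  deltas exceed the analytic mean+3σ of the full pair distribution, while
  all distractors stay below mean+1σ; the ≥5-noise-sd margins on both sides
  make recovery with precision = recall = 1 a deterministic expectation,
  not a lucky draw.
* `T-ADD` (9 compounds, zero noise): exactly additive increments with one
  dual-site pair (Δ 3.3) above its set threshold (3.21) and both hybrids
  present — the decomposition must return *both_contribute/additive* with
  d1+d2 = D to machine precision.
* `T-FLAT` (9 compounds): increments ≤ 0.2, IQR ≈ 0.08 — exercised only as
  gate fodder.
* The `dominant` preset plants a substitution carrying 95% of the dual
  delta; its IQR is below 1 by construction, so decomposition tests run it
  with `min_iqr = 0`.

What the fixtures do **not** emulate: realistic chemical diversity,
stereochemistry, tautomers, charged species, assay noise structure beyond
i.i.d. Gaussian, activity curation (the pipeline assumes pKi-only input),
or database-scale series overlap. Passing tests on these fixtures
demonstrates algorithmic correctness of fragmentation, series assembly,
thresholding and decomposition — not performance on a public bioactivity
database, which additionally depends on curation rules outside this
package's scope.

Problem sizes were chosen so the full suite (including a brute-force
fragmentation cross-check over ~60 molecules and two complete pipeline
runs) completes in about a minute: series of 9–28 compounds exercise every
code path — multi-series sets, H-enrollment, deduplication across
overlapping cores, both cliff categories, and all decomposition outcomes —
while keeping combinatorics at desk scale.

## Numerical and degenerate-input conventions

* Canonicalization is OpenBabel's canonical SMILES; determinism across
  runs and platforms follows from its canonical atom ranking. Fragment
  SMILES go through a 0D SDF path in which stereo wedges are not
  preserved, so cores and substituents are compared constitutionally;
  compound identity (upstream) still distinguishes stereoisomers.
* Fragments that fail sanitization after cutting are discarded and the
  split dropped (logged), rather than emitting unparsable cores.
* Sets with < 2 compounds, series with < 2 members, and sets with < 2
  analog pairs are excluded at their respective stages with log entries;
  an all-equal delta distribution yields sigma 0 and threshold = mean.
* Pair ordering ties (equal pKi) break lexicographically by compound id;
  all stage outputs are sorted, and no output contains timestamps, so a
  rerun from the manifest is byte-identical.
* Aromaticity perception (used by the aromatic-N and biaryl rules) comes
  from ChemmineR ring perception; atoms outside standard-valence elements
  are conservatively treated as having no free valence during
  hydrogen-site enrollment.

## Known limitations

* Cores with reflection-free symmetry can over-count differing sites for
  specific substituent arrangements (upper-bound behaviour, see above).
* Quaternary-nitrogen cuts depend on formal charges surviving the SDF
  round trip; exotic valence states outside the default table are not
  enrolled as hydrogen-bearing sites.
* The (R)MMP mode applies the same mean+2σ threshold as the
  analog-series mode rather than an independently fitted one; a constant
  threshold (e.g. 2 pKi units for the classical 100-fold criterion) is
  available as a comparison flag (`constant_threshold`) but is not a tested
  mode.
* Replicate aggregation and standardization choices (mean, largest
  fragment, retained stereo) are defaults where the method description is
  silent; all are configurable and recorded in the run manifest.
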