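---
title: "Finding the missing gut microbes of malnourished children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the missing gut microbes of malnourished children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromiss)
library(dplyr)
```

## The problem

Children with kwashiorkor — the oedematous form of severe acute
malnutrition — carry a profoundly altered gut microbiota. Two observations
make this analytically tractable even with very few subjects. First, a
stool sample can be profiled by two independent modalities: culturomics
(high-throughput culture under many conditions, with mass-spectrometry
identification of every colony) yields a list of *viable* species per
sample, while 16S rRNA amplicon sequencing yields OTU read counts with
reference identity scores. Second, the scientific target is qualitative:
which species are present in healthy children's guts, by both methods, but
absent from the cases? Those species — especially the obligate anaerobes
among them — are candidates for a therapeutic probiotic mixture.

`micromiss` implements that comparison end to end: OTU post-processing,
presence/absence β-diversity, trait-partitioned Shannon diversity,
accounting of the hitherto-unknown diversity, a small-sample test battery,
and the missing-repertoire screen. A synthetic-community generator makes
every stage testable without any external data.

## Data model

Three tabular structures cover all inputs (all read and written as
UTF-8 TSV with a header):

* a **species catalog**: one row per species with taxonomy (phylum to
  genus), an obligate-anaerobe flag, a novelty class (`known_gut`,
  `known_human_not_gut`, `known_not_human`, `new_species`, `new_genus`,
  `new_family`) and literature-based probiotic-candidacy columns;
* a **detection matrix**: long rows `(sample_id, group, species)` per
  modality (a wide 0/1 dialect is auto-detected on read). Group labels are
  fixed internally to `case`/`control`; file vocabularies ("kwashiorkor",
  "healthy", ...) are mapped through a user alias table, which keeps file
  vocabulary out of the logic;
* an **OTU table**: `(sample_id, otu_id, read_count, best_hit_species,
  best_hit_identity)` with identities as fractions in [0, 1].

Culture and sequencing name the same organism inconsistently, so species
matching is case-insensitive after whitespace collapsing, and abbreviated
binomials ("B. subtilis") are expanded against the catalog when the
expansion is unambiguous. The catalog–name reconciliation is this package's
mechanism; any upstream naming discrepancies should be resolved into the
catalog.

## OTU post-processing rules

Three rules, applied in order, with deliberately asymmetric tie semantics
that follow their usual phrasing:

1. **Low-count filter**: OTUs with *fewer than* 20 reads are removed — an
   OTU with exactly 20 reads survives.
2. **Assignment**: a surviving OTU is assigned to its best-hit species when
   the identity is *at least* 0.97 — a hit exactly at the threshold is
   assigned. Everything else (including OTUs with no usable hit) is
   *unidentified*.
3. **Accounting**: per sample we report the number of distinct species
   detected, the number of unidentified OTUs, the total OTUs after
   filtering, and the assigned-read fraction. Because several OTUs can map
   to the same species, `n_species + n_unidentified_otus <= n_otus` always.

Filtering and assignment are both row-wise, so they commute; the filter is
applied to the table as given (per sample when the table holds per-sample
rows), and the scope can be chosen by how tables are fed in. Whether such a
filter should act per sample or across a pooled run is ambiguous in common
practice; acting on the table as given makes the choice explicit and
composable.

## Diversity statistics

**U/T ratio.** For a group, `U` counts species detected in exactly one
sample of that group and `T` the species detected in at least one;
`U/T` is a presence/absence β-diversity measure — high values mean little
shared community between children. Uniqueness is judged strictly within the
group, regardless of the other group. `T = 0` is an error, not a zero.
Group ratios are compared by treating (U, T−U) per group as a 2×2 table.
The ratio is not fully independent of group size (the chance that a
species is seen exactly once depends on how many samples there are), which
is why the synthetic null-calibration check uses equal group sizes.

**Shannon index.** H′ = −Σ pᵢ log₂ pᵢ, in bits. We use the standard
negative-sum (non-negative) form. On the sequencing side pᵢ are
assigned-read proportions; a culture-side variant on colony proportions is
possible but off by default, since read proportions are the natural
abundance measure here. The oxygen-tolerance partition (anaerobic /
aerotolerant sub-communities) *renormalises* pᵢ within the partition by
default, so each partitioned value is a genuine Shannon index of that
sub-community; `renormalize = FALSE` keeps global proportions and sums only
the in-scope terms, as a sensitivity variant.

**Hitherto-unknown diversity.** Culture side: putative new taxa plus
species not previously known from the human gut, counted from the
catalog's novelty classes. The new-taxon thresholds follow standard 16S
practice: identity to the nearest named species *under* 0.9865 → new
species, *under* 0.95 → new genus; ties at a threshold take the less novel
class ("under" is strict). A new genus or family is counted among the new
species — it is, a fortiori, a species new to science. Sequencing side: the
number of unidentified OTUs (counting OTUs, not reads; the read-level
assigned fraction is reported separately).

## The test battery

All tests are two-tailed and return `mm_test` objects with
`tidy()`/`glance()` methods.

* `chisq_uncorrected()` — Pearson chi-square without continuity
  correction, df = 1. For 2×2 tables the statistic is exactly the squared
  pooled two-proportion z (checked to 1e-10 in the tests). A zero column
  margin degenerates to p = 1 with a warning.
* `fisher_exact_2x2()` — conditional exact test. Two-tailed p by the
  **point-probability** convention: the sum of hypergeometric point
  probabilities not exceeding the observed table's. The doubling
  convention (twice the smaller tail) is available as an option because
  some published tables appear to use it.
* `barnard_exact_2x2()` — unconditional exact test for very small groups.
  The ordering statistic is the pooled-variance two-proportion z; the
  extreme region is `|T| >= |T_obs|`; the p-value is the supremum over the
  common nuisance success probability π of the extreme region's total
  binomial probability, computed on a 2000-point grid over (0, 1) plus a
  local golden-section refinement around the grid maximum. The
  unpooled-variance ordering is available behind a flag for sensitivity —
  it is a genuinely different test and can disagree noticeably. On the
  canonical 10-vs-5 design, the test's exact size at α = 0.05 is just
  below 0.05 (verified by enumeration plus simulation in the tests).
* `pooled_t_test()` — Student's t with pooled variance, df = n₁+n₂−2,
  accepting raw vectors or published summary statistics (mean, sd, n)
  interchangeably. Zero pooled variance is handled explicitly (p = 1 for
  equal means; p = 0 with a warning otherwise).
* `mann_whitney_test()` — exact by exhaustive enumeration of all
  choose(n₁+n₂, n₁) group assignments when n₁+n₂ ≤ 12, with mid-ranks for
  ties and a symmetric-deviation two-tailed rule; otherwise the normal
  approximation with tie-corrected variance and continuity correction.
* `prop_test_one_sample()` — normal-theory z for one binomial proportion.

No false-discovery-rate correction is applied anywhere by default: this is
an exploratory analysis design, and the choice is deliberate and explicit.
An optional Benjamini-Hochberg adjustment can be applied downstream by the
user on the bundle's test log.

The pipeline picks a 2×2 test automatically, since small-cohort practice
mixes them: per-sample presence comparisons with both groups ≤ 10 samples
use Barnard; other 2×2 tables use Fisher when the smallest expected cell is
below 5, otherwise the uncorrected chi-square. Every threshold of the
policy is a config field, and any comparison can be overridden by calling
the test functions directly — the report logs each test with its exact
input table so every number is re-derivable.

## The missing repertoire

`missing_repertoire()` computes

> (control species by culture ∩ control species by sequencing) −
> (case species by culture ∪ case species by sequencing)

"Absent in cases" subtracts the **union** of the case sets: a species seen
by either method in any case sample is demonstrably not missing. On the
control side, one detection per modality suffices by default
(`min_control_samples` raises the bar; presence in a single sample is the
inclusive reading and the threshold makes the stricter readings available).
`annotate_candidates()` joins the result to the catalog and summarises
obligate anaerobes and probiotic candidates. Candidacy is *data*, not
logic: the packaged 45-species repertoire catalog carries the
literature-derived flags (healthy-gut commensal, short-chain-fatty-acid
production, antibacterial or antioxidant function), and user catalogs
supply their own.

```{r repertoire}
cat45 <- missing_repertoire_catalog()
report <- annotate_candidates(cat45$species, cat45)
glance(report)
report$summary$candidates_by_phylum[[1]]
```

## The synthetic generator

`synth_config()` defaults encode the study conditions this pipeline is
meant for: 10 cases vs 5 controls; a shared pool of 300 species (about 100
detected per sample at the default detection probabilities, matching the
per-sample species counts such cohorts report); half the pool obligate
anaerobes; anaerobe detection in cases multiplied by 0.3; Proteobacteria
detection multiplied by 1.9 (the case/control frequency ratio such cohorts
report); unassigned-read fractions of 5% in cases and 26% in controls; and
10,000 reads per sample — enough depth that the ≥20-read filter bites
realistically while 200-seed test batteries stay fast.

Presence is independent Bernoulli per species × sample × modality — the
statistics under test are all presence- or count-based and assume no
co-occurrence structure, so none is simulated. Per-species detectability
varies log-normally (sd 0.3) and is shared between groups, which preserves
exchangeability under null effects while making communities heterogeneous.
Read abundances are log-normal (sigma 1.5) normalised and multinomially
sampled to the configured depth, split into 1–3 OTUs per species; each OTU
is independently "unknown" (identity drawn below 0.97, occasionally with a
missing identity) with the group's configured probability. The
metagenomics detection matrix is then *derived from the simulated OTU
tables by re-applying the ≥20-read and ≥97%-identity rules*, so sequencing
detection honestly reflects what post-processing can see, and species can
legitimately disagree between modalities.

`force_control_only = k` engineers k species detected in every control
sample by both modalities and in no case sample (their OTUs are guaranteed
at least 20 assignable reads, depth-compensated from the deepest other
species), giving the repertoire screen a known ground truth.

What the generator does **not** emulate: species co-occurrence and
phylogenetic structure, chimeras and sequencing error, protocol batch
effects, longitudinal dynamics, and compositional read-count correlations
beyond the shared multinomial depth. Tests passing on synthetic data
therefore validate the *computational* pipeline and its statistical
calibration, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Threshold ties: `>= 20` reads kept, `>= 0.97` assigned, novelty "under"
  strict — each matches the rule's phrasing.
* Barnard's extreme region uses a 1e-10 tolerance on `|T|` comparisons so
  floating-point ties land inside the region; the statistic is defined as 0
  where the pooled variance vanishes (all-success or all-failure margins),
  which makes the degenerate all-equal table return p = 1.
* The nuisance grid has 2000 points by default; the grid maximum is refined
  with `optimize()` on the bracketing interval. Printed two-decimal
  p-values of the canonical small tables are stable from roughly 100 grid
  points on.
* Fisher's point-probability comparison uses a relative 1e-7 slack, the
  same guard standard implementations use against spurious strict
  inequalities.
* Exact Mann-Whitney enumeration is capped at n₁+n₂ = 12 by default
  (924 assignments); the cap is a parameter, not a hidden constant.
* All-zero abundance vectors, empty groups, zero margins and missing
  catalog species raise errors (or warnings where the spec of the
  operation calls for tolerance) rather than propagating NaN.

## Problem sizes used in the test battery

The packaged checks run at desk scale: exhaustive Fisher-vs-enumeration
agreement over all 134,030 2×2 tables with N ≤ 40; exact Mann-Whitney
against full permutation enumeration for n₁+n₂ ≤ 12; Barnard's simulated
size from 10,000 null tables on the 10-vs-5 design (via exact p-values of
all 66 possible tables); effect-direction recovery over 200 generator
seeds at the default configuration; and null calibration of the anaerobe
U/T chi-square over 500 seeds with equal groups of 6 and a 120-species
pool.

## Known limitations

* The U/T ratio's mild group-size dependence means its chi-square is
  approximate for unequal groups; the package reports it as the field
  does, and the calibration evidence is for equal groups.
* Shannon inputs on the sequencing side are read proportions of *assigned*
  species; if most reads are unassigned (as in the healthiest samples),
  the index describes the known fraction of the community only.
* Two-tailed exact-test conventions differ across software; the Fisher
  doubling option and the Barnard unpooled option are provided so users
  can reproduce other tools' numbers, but the defaults are the
  conventions stated above.
* The probiotic-candidate flags are curated literature judgements packaged
  as data; the package does not attempt to derive them.
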