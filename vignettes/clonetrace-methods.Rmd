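---
title: "Methods: simulating and analysing clonal organoid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing clonal organoid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The problem

Bulk tumour sequencing averages over subclones: a mutation carried by a
minority of cells appears at low allele frequency or not at all. Deriving
organoids from *single* tumour cells removes this averaging — every somatic
variant a founding cell carried is clonal in its organoid, so heterozygous
variants sit near 50% VAF and presence/absence across organoids becomes an
essentially error-free binary character. clonetrace implements the analysis
chain that exploits this design (sharing classification, spectra,
enrichment tests, copy-number segmentation, perfect-phylogeny
reconstruction, rate regression) together with a simulator that generates
data under the dynamics such studies infer, so each stage can be tested
against known truth.

## The simulated world

`sim_config()` fixes the generative model; its defaults are the stated
conditions of the emulated study design, chosen once:

* **SNS rate** `sns_rate_per_week = 0.8` coding+splice substitutions per
  lineage per week, so a 25-week tumour lineage carries ~20 coding SNSs —
  the magnitude seen in late-sacrificed tumours. The rate is *constant in
  time and independent of genotype*: this is the model's central
  assumption, and the simulator enforces it exactly (a Poisson process on
  each branch). SNSs are placed genome-wide at intensity
  `rate / coding_splice_fraction(genome)`, so by Poisson thinning the
  coding+splice count has exactly the configured mean.
* **Normal-cell rate** `normal_sns_rate_per_week = 0.08`. The tumour:normal
  ratio is not quantified by the emulated study beyond "significantly
  fewer"; we default to 10x, the order of magnitude reported for
  precancerous vs normal intestinal organoids, and expose it as a plain
  config field rather than asserting it in tests.
* **Signature mixture** `(sig1_like, sig17_like, uniform) =
  (0.55, 0.15, 0.30)`: signature 1 dominant, signature 17 present but
  weaker, plus a flat remainder. Reference profiles are built from verbal
  definitions — 90% of sig1-like mass uniformly on the four NpCpG C>T
  classes, 80% of sig17-like mass on CpTpT-context T>G/T>C — not from a
  downloaded catalogue, keeping the package fully offline. Users can
  substitute real catalogue vectors via `reference_profiles(path)`.
* **CNA gating**: `cna_rate_per_week_tp53null = 0.15`,
  `cna_rate_per_week_tp53wt = 0`. The wild-type rate of exactly zero makes
  the genotype gating a *hard invariant* (tested as such); 0.15/week gives
  a 25-week Tp53-null lineage ~4 events, the per-organoid scale observed
  in late tumours. CNA lengths are log-uniform on 5–80 Mb scaled by
  `genome_scale = 0.02` (toy chromosomes are 2 Mb standing in for a
  nominal 100 Mb), so both sub-threshold and large-scale (>10 Mb
  equivalent, i.e. >200 kb toy) events occur. The scale factor is recorded
  in the config so the large-scale threshold keeps its meaning.
* **Drivers** switch at scheduled times on *all* extant lineages
  (recombinase induction acts tumour-wide), which keeps genotype flags
  monotone along every root-to-leaf path.

What the generator does *not* emulate: sequencing error beyond binomial
sampling, germline contamination, mapping artefacts, selection or fitness
differences between clones, chromatin/GC structure, and real genome
repeat content. A green test therefore establishes correctness of the
analysis operations under clean clonal dynamics — not robustness to
caller-level noise.

## Numerical and design choices

**SNS placement.** Contexts are drawn from the signature mixture, then a
genomic position is drawn uniformly among positions whose
pyrimidine-collapsed triplet matches the drawn class, via a per-genome
precomputed context index. This is distribution-identical to rejection
sampling against the genome sequence but ~100x faster on the 6 Mb default
genome. Placement biases (late-S replication timing, large genes) are
applied by thinning against the maximal weight, again preserving the
target distribution. Infinite sites is enforced with a used-position
registry; a genome lacking a requested triplet class fails loudly naming
the class.

**Copy-number bookkeeping.** Each clone's state stores, per variant, the
number of mutated and total copies at its locus. A gain duplicates the
mutated copy with probability `mut/tot`; a loss removes it with the same
probability — so a heterozygous variant inside a one-copy loss ends at
VAF 1 (copy retained) or disappears (copy lost). Overlapping CNAs on one
lineage are redrawn, keeping the arithmetic unambiguous.

**Consequence annotation** translates the reference and mutated codon on
the coding strand with the standard genetic code; splice sites are the two
intronic bases flanking internal exon boundaries (the canonical
donor/acceptor dinucleotides; the window is a parameter because the
emulated analysis never states its own). CDS positions are never labelled
splice site. The unit tests check 200 random exonic substitutions per
strand against an oracle that rebuilds and translates the entire CDS.

**Presence tiers** default to 3 supporting reads and 10%/20% VAF cut-offs,
mirroring the saturation tiers used in published heat-map renderings of
biopsy presence; any non-absent tier counts as present for matrix building.

**Sharing classes** are defined over organoids only; biopsies are carried
along but never influence trunk/semi-private/private labels. With two
organoids, trunk and "shared" coincide and the result says so.

**Segmentation** is a simplification of circular binary segmentation:
at each recursion step all candidate sub-segments are scanned *jointly over
both boundaries* against the rest of the current segment (the single-point
variant mislocalises the second boundary of interior events), the split is
accepted at `|t| >= 5`, and every piece keeps at least 5 bins. The noise
scale in the t statistic is estimated once per chromosome from the median
absolute successive difference (robust to level shifts; per-segment
re-estimation proved unstable on short segments and caused over-splitting).
There are no permutation p-values; acceptance is by planted-change-point
recovery (boundaries within ±2 bins) and a null false-positive bound
(<0.1 spurious segments per genome at the default threshold).

**Panel-of-normals filtering** removes a tumour segment when a same-call
normal segment achieves 50% reciprocal overlap; the criterion is a package
choice (the emulated pipeline states only that normal-tissue CNAs were
excluded) and is exposed as a parameter. The operation is idempotent.

**Gene-size enrichment test.** Grouping is by *genomic span* at 150 kb;
assignment weights are by *coding length* — the two deliberately differ,
following the test's published description. "More than observed" is read
literally as a strict inequality; `greater_or_equal` is offered because
the wording could be loose, and no +1 continuity correction is applied
(the literal count is implemented; the option is noted here rather than
silently added). Because assignments are independent Bernoulli draws, the
Monte-Carlo p-value converges to a binomial tail, which `exact_tail()`
provides as the independent oracle.

**Signature decomposition** solves non-negative least squares between the
unit-normalised spectrum and the reference profiles by the Lawson–Hanson
active-set iteration — exact at these sizes, so the residual is zero to
machine precision whenever the spectrum lies in the references' cone.
Weights are reported rescaled to sum 1.

**Triplet normalisation** divides each class count by the territory
prevalence of its underlying triplet and rescales so the total is
preserved. Whether the emulated analysis rescales after dividing is not
recoverable from its text; total preservation is our documented choice
(it keeps raw and normalised spectra comparable on one axis). Census and
spectrum share a single pyrimidine-collapse convention applied at census
time, so numerator and denominator can never disagree on strand handling.

**Phylogeny conflicts** are resolved greedily: character groups (merged by
identical carrier sets) are admitted in order of descending support,
ties broken by lexicographically smallest sample set, and any group
overlapping a kept group without nesting is excluded and reported with its
conflicting partners. This generalises "exclude the characters that cannot
be placed" to arbitrary inputs while reproducing the published choice on
the worked example (exactly the two characters crossing the major branch
split are excluded). Metastasis samples participate as ordinary leaves;
samples with identical profiles stay separate sibling leaves. Newick
output orders children by smallest leaf label, making the serialisation
canonical: write–read–write is the identity.

**Replication timing** uses three strata (early/mid/late) in the fixture,
though downstream comparisons usually contrast early vs late only; mid-S
interpretation is left to the user, matching the ambiguity in the emulated
analysis's own description.

## Worked-example fixtures

`inst/extdata` ships two tiered presence matrices. The two-organoid
fixture encodes 14 shared and 2+6 private variants. The eleven-sample
fixture (7 organoids, 4 metastases) encodes a trunk of 4 SNSs plus a
truncal CNA, three branches off the trunk, nested subbranches, two
deliberately conflicting characters carried by 3 organoids across the
major branch split, and metastasis profiles yielding exactly 3 distinct
patterns. Group sizes that the emulated study leaves unstated (the private
branch of one organoid, the deepest subbranch characters) are set to
plausible small values — the tests assert only quantities that are fully
determined: trunk size, root out-degree, conflict set, seeding-event count.

## Acceptance and budgets

`scripts/acceptance.R` recomputes the stochastic acceptance target (mean
organoid VAF at heterozygous copy-neutral sites, in percent) from scratch:
20 independent 25-week Tp53-wild-type lineages on a compact 500 kb genome,
each carrying ≥100 substitutions, sampled at 100x. The compact genome is a
speed choice only — VAF behaviour does not depend on genome size. The test
suite scales its simulations similarly (shorter durations, smaller
genomes) to stay inside a single-CPU desk budget; every tolerance is the
spec-stated one, not tuned to observed outcomes. One statistical bound was
derived rather than copied: the Kolmogorov–Smirnov check of null p-value
uniformity uses threshold `max point mass + 1.63/sqrt(n)`, since a
binomial-discrete p-value cannot beat its own largest atom.

## Known limitations

* Binary segmentation has no statistical significance per segment
  (no permutation p as in full CBS); the t threshold is a fixed tuning.
* The phylogeny requires binary presence; low-purity biopsies can drop
  below presence thresholds and prune true clades — the organoids-only
  mode exists for that reason.
* `run_analyze()` consumes the in-memory cohort; the on-disk dataset
  written by `simulate_cohort(out_dir=)` is for interchange and recovery
  tests, not a second analysis entry point.
* No indels, no multi-nucleotide variants, no germline/somatic calling,
  no purity or ploidy estimation.
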