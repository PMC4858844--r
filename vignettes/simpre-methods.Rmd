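---
title: "Calling significantly mutated protein regions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling significantly mutated protein regions: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpre)
library(data.table)
```

## The problem

Somatic mutation catalogs from tumor sequencing are dominated by passenger
events with no selective role. Driver mutations, by contrast, tend to
recur in localized protein segments — an activation loop, a degron, a
binding interface — because only changes there confer a growth advantage.
`simpre` detects such segments directly from the positional distribution
of missense point mutations and in-frame insertions/deletions along each
protein, without gene-level priors, annotation-predefined region
boundaries, or an external estimate of the neutral mutation rate.

The package covers the full path from a raw cohort table to annotated
region calls: input cleaning, the enrichment scan itself, significance
tiering, dominant-mutation-type and cancer-type labeling, a
randomization test for co-occurrence of called regions with functional
annotations, and amino-acid substitution-rate summaries. A synthetic
cohort generator makes every stage testable without access to any
external mutation database.

## The enrichment model

The null model is deliberately minimal: within one gene, neutral
mutations are assumed to fall uniformly along the sequence, with the
gene's own observed mutation count setting its background. This makes
the per-gene background self-calibrating — heavily mutated genes need
proportionally stronger clustering before a region is called.

For a candidate interval of `len_in` residues carrying `m_in` of the
gene's events (the remaining `m_out` events fall on the other `len_out`
residues), evidence of local enrichment is the one-sided Fisher's exact
test on

|                | mutation events | residue positions |
|----------------|-----------------|-------------------|
| inside region  | `m_in`          | `len_in`          |
| outside region | `m_out`         | `len_out`         |

i.e. the hypergeometric upper tail at `m_in`. An event counts inside
when its closed span intersects the interval — an indel is one event
however many residues it deletes, and is never split across the
boundary. Two degenerate cases return p = 1 by construction: an empty
interval (`m_in = 0`) and an interval covering the whole protein
(`len_out = 0`), neither of which can carry evidence of *local*
enrichment.

```{r pvalue}
region_pvalue(m_in = 5, m_out = 5, len_in = 10, len_out = 90)
```

A binomial-tail variant (`region_pvalue_binomial()`), with each event
landing inside independently with probability `len_in/(len_in+len_out)`,
is exported as a cross-check; the two agree closely in the sparse regime
the scan operates in and the exact test is always the one used for
calling.

### Scan, boundary optimization, merging

Every window of 7, 10 and 30 residues is tested (a protein shorter than
a seed length contributes its single full-length window, so short
proteins remain scannable). The three seed sizes bracket the scales of
functional elements: short linear motifs, small surface patches, and
domain-sized segments. Windows with p below the gate `alpha = 0.01` are
seeds.

Each seed is then refined by a greedy hill-climb: of the four
single-residue boundary moves (extend/shrink, left/right) the one with
the lowest p is applied if strictly lower than the current p, until a
local optimum. Ties between improving moves break to the shorter
resulting interval, then to the leftward one — arbitrary, but fixed, so
calls are reproducible. Optimized intervals that overlap are unioned
transitively and the p-value recomputed once on each union. A merged
span can in principle exceed the gate even though each constituent
passed it; such regions are retained but flagged (`above_alpha`) rather
than silently dropped or silently kept, since the behavior is a
consequence of merging rather than of the evidence in any one seed.

No multiple-testing correction is applied across windows or genes: the
gate operates on raw p-values. This is a deliberate design property of
the method, not an oversight — the low-significance tier is expected to
contain false positives, and the tiering exists precisely to stratify
confidence. The acceptance script quantifies this on null cohorts (see
below).

### Tiers, dominant type, cancer types

Called regions are tiered by total p-value: high (p ≤ 1e-20), medium
(1e-20 < p ≤ 1e-5), low (1e-5 < p < 0.01). A p-value exactly on a bound
goes to the more significant tier. The per-type p-values recompute the
same table restricted to each mutation class alone; the class with the
lowest restricted p is the region's dominant type (ties resolve
missense > deletion > insertion). Cancer-type labels of the mutations in
a region are tallied in full, and every label contributing at least
`min_fraction = 0.2` of the region's events is reported as associated —
no principled cutoff exists for this labeling, so the fraction is a
configurable reporting threshold, not a statistical claim.

## Input cleaning

Four cohort-level filters run in a fixed order before calling, each with
an auditable removal report:

1. **Hypermutated samples** — samples with more than 100 mutations
   across the whole cohort (not per gene) are removed entirely; exactly
   100 is kept. Such samples are dominated by passengers and would
   inflate every gene's background.
2. **Common SNPs** — missense events at listed SNP positions are
   removed; indels are untouched, since the rule exists to catch
   germline point variants mislabeled as somatic.
3. **Clonal duplicates** — samples with ≥ 5 mutations sharing ≥ 50 % of
   their distinct variations (fraction relative to the smaller sample's
   variation set; identity on isoform, coordinates, type and alternate
   residue) are grouped by transitive closure and only the most
   mutation-rich member of each group is retained, collapsing duplicate
   database entries and sequencing of the same clone. Richness ties
   break to the lexicographically smallest sample ID.
4. **Low complexity** — events whose span intersects a listed
   low-complexity interval are removed (alignment and sequencing
   artifacts concentrate there).

The SNP and low-complexity exclusions are consumed in protein
coordinates; lifting genome-space resources into protein space is
upstream curation, which keeps the package free of genome-annotation
dependencies. Filter order matters on adversarial inputs (a clonal pair
could drop below the 5-mutation floor after SNP removal), so the order
is fixed and documented rather than configurable.

Isoform handling is equally mechanical: per gene, the isoform carrying
the most mutations is the analysis isoform (ties to the
lexicographically smallest ID), and mutations mapped only to other
isoforms are dropped and counted. Re-mapping them across isoforms would
require alignment information the input table does not carry.

## Annotation enrichment by matched randomization

Whether called regions co-occur with functional annotation (domains,
motifs, active sites, ...) is tested against a randomized baseline that
preserves the structural context of each region: every region is
re-placed on a protein whose length and disorder content both match the
source protein within ±10 % (relative), at a uniformly drawn position,
1000 times. The observed overlap — the number of regions intersecting at
least one interval of a category — is compared to the randomized
distribution in standard-deviation units, `z = (obs − mean)/sd`, with
|z| ≥ 2.326 flagged (one-sided p < 0.01 under normality of the
randomized counts, which hold well at these sizes). A residue-level
overlap statistic is emitted alongside, since "overlap" can reasonably
be counted either way; the region-count statistic is the primary one.

Matching on disorder requires per-residue disorder calls. Raw predictor
scores are smoothed by a 31-residue centered moving average (truncated
at the termini); a residue is disordered when the smoothed primary score
or the raw binding-region score exceeds 0.5, unless it lies in an
annotated domain, which overrides the call. The 31-residue window
reflects the length scale over which disorder is meaningful; the domain
override prevents locally ambiguous scores inside folded domains from
counting as disorder.

Two numerical guards: proteins with disorder content below 0.05 are
matched with an absolute ±0.05 band (a relative band around ~0 would
match nothing), and a region wider than every matched protein is
skipped in that randomization and counted in a skip report rather than
silently dropped. All placements flow from one seeded generator,
region-major, so results are reproducible bit for bit and adding a
category does not perturb placements.

## Substitution rates

For missense events, each distinct substitution is counted once per
position (R→H at residue 175 seen 300 times is one event; R→H and R→L
at the same position are two). Percentages are
`R[i,j] = 100 * n[i,j] / N` over the 20×20 standard residues;
substitutions involving nonstandard letters (U, X, B, Z) are excluded
from the matrix and tallied separately. With a region set supplied the
matrix is computed separately for events inside and outside regions;
the two Ns always partition the total exactly.

## The synthetic cohort generator

`simulate_cohort()` emulates precisely the statistical structure the
caller assumes: per-gene uniform background with count
`Poisson(L × rate)`, and planted hotspots adding
`Poisson(width × rate × fold)` events uniformly within their interval.
The default type mix puts 97.6 % of events on missense, matching the
point-mutation/indel ratio of large somatic catalogs. Confounders
(hypermutated samples, clonal pairs, SNP-coincident and
low-complexity-overlapping events) are constructed to trigger each
filter exactly, and every non-confounder event gets its own sample ID so
no filter fires spuriously. All randomness derives from one seed through
pre-drawn per-gene sub-seeds, so extending a cohort does not perturb
earlier genes. An adversarial mode (`nonuniform_background`) applies a
4× linear intensity ramp along each sequence to characterize — not
pass — robustness of the uniform-background assumption.

What the generator does **not** emulate: trinucleotide mutational
signatures, replication-timing and expression covariates of the local
rate, sample-level correlation of mutations, or realistic protein
length/disorder distributions. Passing the simulation benchmarks
therefore demonstrates correctness of the statistics under the model's
own assumptions, not performance on real cohorts.

## Calibration and known limits

The test suite and `scripts/acceptance.R` exercise the pipeline at fixed
problem sizes chosen to keep a full run within minutes on one core: a
recovery benchmark of 200 genes (L = 1000, background 0.01
events/residue, one 15-residue plant at 20× background), a null cohort
of 1000 genes at the same geometry, and enrichment calibration on a
200-protein proteome with 1000 randomizations.

Two behaviors of the method under these conditions are worth stating
plainly, because they are properties of the data regime rather than
implementation artifacts:

* **Sensitivity is bounded by event sparsity.** A 15-residue plant at
  20× a 0.01 background receives `Poisson(3)` events: about one plant in
  five receives ≤ 1 event, and a single event cannot reach p < 0.01
  against a ~10-event gene background at any window size. Overall
  recovery on this benchmark is therefore ~75 %, rising above 90 % for
  plants that received at least two events — the caller finds
  essentially every plant that is statistically identifiable, and the
  shortfall is irreducible at these rates.
* **The low tier is permissive by design.** With ~10 background events
  on 1000 residues, two events within a 7-residue window already clear
  the 0.01 gate, so roughly half of null genes yield some
  low-significance call. The acceptance script reports this fraction
  against the documented bound (five times the naive any-window
  expectation, capped at one). Consumers who need cohort-level error
  control should treat low-tier calls as candidates, which is how the
  tiering is intended.

Other deliberate numerical choices: boundary p-value ties during
optimization prefer shorter-then-leftward intervals; the dominant-type
tie priority is fixed; tier boundaries go to the more significant tier;
`scan_config()` validates that seed lengths are positive and the gate is
in (0, 1). All thresholds (100, 5, 0.5, 7/10/30, 0.01, the tier bounds,
31, 0.5, 0.1, 1000, 2.326) are surfaced as named configuration keys
defaulting to the values above.

## Worked example

```{r example}
spec <- sim_spec(
  n_genes = 4, length_range = c(500L, 700L), background_rate = 0.01,
  plants = list(list(gene = 2, start = 150, width = 12, fold = 40)),
  rng_seed = 7
)
cohort <- simulate_cohort(spec)
cleaned <- clean_mutations(cohort$mutations, cohort$exclusions)
regions <- call_regions_cohort(build_gene_sets(cleaned$mutations,
                                               cohort$sequences))
regions[, .(gene_id, start, end, p_total, tier, dominant_type, n_mutations)]
```

The planted hotspot on the second gene is recovered as a region
overlapping residues 150–161; background-only genes may contribute
low-tier calls, as discussed above.
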