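---
title: "Clonal structure and hybrid parentage in mixed-ploidy microsatellite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal structure and hybrid parentage in mixed-ploidy microsatellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apomixr)
```

This vignette is the package's own account of the methods it implements:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The data model

All arithmetic runs on **allele repeat counts**, not fragment sizes in
bp. The stepwise mutation model underlying the Bruvo distance is defined
on repeat counts, so fragment sizes must be divided by each locus's
repeat motif length (after subtracting any constant flanking offset);
`read_genotype_table()` does this on input, using integer division. The
conversion constants are marker properties the user must supply — they
cannot be inferred from the data.

A genotype is, per locus, a multiset of *distinct* observed alleles.
Allele dosage in polyploids cannot be resolved from fragment data alone
(a tetraploid showing two peaks may be AABB, AAAB or ABBB), so copy
number is deliberately left unresolved and no method here requires it. A
locus that fails to amplify is an empty set and is excluded, pairwise,
from genotype distances.

## Bruvo distance

The allele kernel `1 - 2^-|a-b|` encodes a geometric prior on stepwise
mutation: each extra repeat step halves the probability of relatedness.
For two same-size allele sets the locus distance is the minimum over
perfect matchings of the mean kernel value. With sets of different size
(different ploidy, or unresolved dosage) there are two classical
reconciliations:

* **genome loss** — the larger genotype is assumed to have gained
  nothing; the smaller is padded with virtual alleles at distance 1 from
  everything (an infinitely distant allele);
* **genome addition** — the smaller genotype is padded with copies of
  its *own* alleles, chosen to minimise the distance (a duplicated
  genome);
* **combined** — the arithmetic mean of the two.

The default is `combined`: when the direction of a ploidy change is
unknown — the usual situation in a reticulate complex where triploids
form both "up" from diploids and "down" from tetraploids — averaging the
two models is the neutral choice. The choice matters only for pairs of
unequal allele-set size and is recorded in the pipeline manifest; both
one-sided models remain available as explicit options.

Matching is solved by exhaustive enumeration over permutations (and,
for the addition model, over pad multisets). With at most tetraploid
genotypes every matching problem has size ≤ 4, i.e. ≤ 24 permutations:
correctness is trivially auditable and speed is a non-issue. A bitmask
dynamic-programming assignment solver is included as a fast path and is
required by the test suite to agree exactly with the enumeration on
10,000 random genotype pairs. The distance matrix evaluates each locus
once per unique pair of single-locus profiles and expands the result;
in clonal data this collapses hundreds of samples to a few dozen
profiles, which is why a 207-sample, 13-locus matrix takes seconds.

## Clonal analysis

**MLGs** are connected components at distance exactly zero — any
non-zero distance separates MLGs. **Clonal lineages** are single-linkage
components under `d ≤ t`. Single linkage is the right closure here
because "clone-mate" is a chain relation: if B is A's somatic mutant and
C is B's, then A and C belong to the same lineage no matter their direct
distance. A consequence worth knowing: one intermediate genotype can
bridge two otherwise distant clusters.

**Threshold detection.** The histogram of all pairwise distances in a
clonal data set is multimodal: a large peak at or near zero (identical
genotypes plus somatic mutants and scoring error) and further peaks for
distinct but related genotypes from separate sexual events. The
threshold is taken at the *valley*: the centre of the minimum-count bin
strictly between the modal bin nearest zero and the next local maximum.
Concretely the implementation (i) bins at width 0.01 by default, (ii)
smooths counts with a 3-bin moving average so single noisy bins do not
masquerade as peaks, (iii) takes the first peak as the modal bin
(ties resolve toward zero), (iv) takes the second peak as the
highest later bin preceded by a strict dip, and (v) returns the middle
bin of the first minimal run between the two. On a plateau of empty
bins this lands mid-valley rather than hugging either peak. A unimodal
histogram yields `NA` plus a warning — the caller must then supply a
threshold manually (`threshold_override` in the pipeline), and the
manifest records which source was used. Bin width and smoothing window
are exposed because neither is canonical; 0.01 resolves valleys an
order of magnitude narrower than typical between-lineage distances
(~0.1–0.5) while keeping bins populated at realistic sample sizes.

The histogram tallies all `n²` ordered comparisons including
self-comparisons, matching the bookkeeping convention under which such
histograms are usually published; self-distances are excluded from
clustering itself.

**Diversity.** Simpson's complement uses the unbiased
without-replacement estimator `1 - Σ n_i(n_i-1)/(N(N-1))`: the
probability that two individuals drawn without replacement carry
distinct MLGs. The biased plug-in `Σ(n_i/N)²` form is behind a flag for
cross-checks only. Rarefied allelic richness resamples without
replacement (default 1000 replicates); the seed is a mandatory argument
because an unseeded Monte-Carlo statistic is not reproducible.

## Ordination and trees

Both PCoA and neighbor-joining run on **MLG representatives** (the
lexicographically smallest sample id of each MLG — an arbitrary but
deterministic tie-break), not on all samples: a clone of 30 identical
individuals would otherwise contribute 30 identical points and drag the
axes toward it.

PCoA is classical metric scaling: Gower double-centering of `-d²/2`,
eigendecomposition, coordinates scaled by the square root of positive
eigenvalues. Bruvo distances are not guaranteed Euclidean-embeddable, so
negative eigenvalues can occur; they are reported but **not** corrected
by default (no Cailliez/Lingoes constant), because correction changes
all distances and the axes are used for visual grouping, not for
downstream inference. Percent variance is reported relative to the sum
of positive eigenvalues.

Neighbor-joining follows Saitou–Nei with the Q-criterion. Two numerical
choices: ties in Q break deterministically toward the lowest index pair,
so runs are exactly reproducible; and negative branch lengths — an
artifact NJ produces on non-additive input — are clamped to zero with
the deficit moved to the sister edge, which preserves all path lengths
through the joined node. On additive matrices the input distances are
recovered to numerical precision (the suite checks 200 random 5–8 taxon
trees at 1e-9).

## Parentage scoring

A candidate parent pair is scored by the number of the target's alleles,
summed per allele over scored loci, missing from the union of the two
parental pools. Counting per allele (a locus with two uncovered alleles
contributes 2) preserves information a per-locus count would flatten.
Pools follow the breeding system: an apomict's founding genotype is
assumed extant, so its pool is the majority MLG (optionally widened by
all minority variants for a second, "next best match" pass, or at
designated hypervariable loci); a sexual outcrosser's founding genotype
is presumed gone, so its pool is every allele sampled in the taxon.
Score zero is necessary, not sufficient, evidence of parentage: allele
sharing across related taxa means several pairs can reach zero, and all
tied pairs are reported. No ploidy-arithmetic feasibility filter is
applied by default — presence matching is the primary signal — and
self-pairs are excluded unless requested.

Genome-specific loci give an orthogonal check: markers that amplify from
only one ancestral genome count that genome's contribution directly, so
a triploid from a reduced diploid egg and a reduced tetraploid pollen
grain shows a `2:1` allele ratio, tetraploids of dual ancestry `2:2`,
and pure-subgenus tetraploids `4:0`. Non-amplification at such a locus
is informative (the genome is absent) and is reported as a flagged zero,
not an error.

## Flow-cytometry ploidy

Inputs are peak summaries (means and CV%), not raw FCS histograms —
peak calling is an instrument-side task. Relative 2C is the
sample/standard peak ratio times the standard's genome size; ploidy is
`round(2 × 2C / reference 2C)` accepted within a tolerance of 0.25 on
the continuous estimate. That default is deliberately asymmetric-ish in
effect: tetraploid genome sizes drift downward relative to doubled
diploid values (genome downsizing after polyploidisation), so observed
tetraploid ratios sit well below 4.0 and a tight tolerance would
misflag them, while 0.25 still rejects midpoints between cytotypes.
Records outside tolerance are flagged ambiguous and excluded from
cytotype summaries rather than silently assigned. The base chromosome
number defaults to `x = 17` (Maloideae); the diploid reference 2C is a
configuration value, typically the mean of confirmed diploids in the
same run, and one reference is supported per run.

## The synthetic generator

`simulate_study()` emulates the statistical structure of a reticulate
apomictic complex so that every stage is testable with ground truth:

* two sexual diploid taxa (13 and 33 samples) whose individuals are
  independent draws — each gets a unique MLG with overwhelming
  probability;
* seven apomictic polyploid taxon entries (161 polyploid samples in
  all): two ancient founder tetraploids drawn directly from the allele
  frequencies, and five hybrids with recorded parent pairs and gamete
  sizes — including a triploid from a reduced diploid egg × reduced
  tetraploid pollen, and two tetraploids formed over that triploid
  bridge from unreduced triploid gametes;
* one two-sample entry sharing its taxon label with another, so one
  labelled taxon truly contains two lineages of separate origin;
* per-locus truncated-geometric allele frequencies over 8–24
  repeat-count states, mimicking observed allele counts per locus in
  such marker panels, with flatter frequencies at the two
  genome-specific loci;
* clonal propagation under the ±1 stepwise mutation model (equal
  probability up/down; homoplasy emergent, never prevented), with the
  number of mutant variants fixed per taxon below 19% of samples so
  the >80% majority-MLG dominance that defines the study system is a
  planted property, not a hope;
* three loci that fail to amplify in the diploids (so "core"
  10-locus and polyploid-only 13-locus analyses are distinct, as in
  real panels), and genome-specific loci that amplify only in taxa
  carrying the corresponding genome;
* flow-cytometry peaks drawn around planted 2C values of 1.63 pg
  (diploid), 2.33 pg (triploid) and 3.10/3.22 pg (tetraploids; chosen
  within the empirically observed tetraploid range and such that
  classification at the default tolerance is unambiguous by
  construction) with 0.5% relative noise.

Two generator design rules deserve explicit statement. First, gametes
are sampled **without replacement** from the parent's distinct alleles,
and founder draws at genome-specific loci are likewise
without-replacement — ancient allotetraploids are modelled as fully
heterozygous at diagnostic loci. Second, when a hybrid founder takes a
gamete from a sexual population, the crossing individual is chosen to be
*informative* at the diagnostic loci: heterozygous, and carrying alleles
disjoint from the co-gamete's. This mirrors why genome-specific loci are
diagnostic in real systems and makes the planted contribution ratios
(`2:1`, `2:2`) structurally countable rather than subject to sampling
coincidence.

What the generator does **not** emulate — and what passing recovery
tests therefore cannot show about real data: genotyping artefacts
(stutter, null alleles, scoring error beyond stepwise mutation),
facultative sexuality within apomicts, spatial population structure,
linkage between loci, multi-step mutation jumps, and real marker allele
spectra. Recovery of planted structure validates the machinery, not the
biology of any particular data set.

## Problem sizes and determinism

The shipped test suite runs the full generator (207 samples, 13 loci),
10,000 random genotype pairs for the matcher equivalence check, 200
random additive trees for NJ consistency, 20 Euclidean configurations
for the PCoA round trip, and 100 seeded replicates of the
threshold-detection check — sizes at which every check is exact or
near-exact while the whole suite stays comfortably inside a few minutes.
All randomness flows through explicit integer seeds; re-running the
pipeline with the same configuration yields byte-identical outputs
(timestamps live only in the manifest).

## Known limitations

* The addition-model pad search is exhaustive and therefore exponential
  in the allele-set size difference; it is instant for differences ≤ 3
  (the full ploidy range here) but not intended for high polyploids.
* Valley detection assumes the clone peak is the modal bin; in a data
  set dominated by sexual recruits the first peak may not be, and the
  manual override should be used.
* Parentage scoring is presence-based; it cannot distinguish a true
  parent from a taxon that happens to contain the same alleles, and
  likelihood-based paternity analysis is intentionally out of scope.
* One flow-cytometry reference standard per run; cross-standard
  harmonisation is the user's task.
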