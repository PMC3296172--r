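---
title: "Delimiting sibling species with diagnostic nucleotides, monophyly and calibrated divergence times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting sibling species with diagnostic nucleotides, monophyly and calibrated divergence times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Drosophila lini* and its siblings *D. ohnishii* and *D. ogumai* are
morphologically almost indistinguishable but partially reproductively
isolated — a textbook case of species caught early in divergence. For such
groups two standard DNA-barcoding questions arise per locus (here the
mitochondrial ND2 and COI-COII regions and the nuclear ITS1-ITS2 spacers):

1. **Character-based identification.** Does any species carry a *pure simple
   diagnostic* — a nucleotide (or indel) state fixed within that species and
   absent from every other focal species at the homologous site?
2. **Phylogeny-based delimitation.** Is each species monophyletic on the
   locus tree (Neighbor-Joining on Kimura 2-parameter distances, with
   bootstrap support)?

A third question concerns timing: concatenating the loci into a supermatrix
and anchoring one node of known age converts the tree into absolute
divergence times, ordering the speciation events.

`barcodelim` implements all three layers as a tested pipeline, and pairs
them with a seeded generator that produces multilocus datasets with exactly
the features that make this delimitation problem hard: deep within-species
polymorphism, incomplete lineage sorting between very recently split
species, and a polymorphic multi-base indel.

## Character-based diagnostics

Strains are collapsed per species into per-site state sets:
the set at a site is the union of the strains' states, with IUPAC codes
expanded (R = A/G, Y = C/T, ...) and `?` contributing the full set
{A,C,G,T}. The latter is deliberately conservative — missing data widens a
species' state set and can therefore only *destroy* diagnostics, never
create them.

A site is **informative** when it is variable among the focal strains at
all, *including* sites whose only variation is a within-species
polymorphism. This is weaker than parsimony-informativeness; the weaker
definition is the one under which the bundled curated tables for the three
loci are internally consistent (e.g. the ND2 site whose states read A/R/A
is variable only within *D. ohnishii* yet is counted among the informative
sites).

A **diagnostic call** for species $S$ at a site requires both fixation and
exclusivity: $S$'s state set must be a singleton $\{x\}$, and $x$ must not
occur in any other focal species' set there. A species polymorphic at a
site is never diagnosed at it. For indel characters the comparable states
are `present:<motif>` and `absent`; presence with different motifs counts
as different states (again the conservative choice — two species sharing
"an insertion" but not its sequence are not treated as sharing a state).

Indel characters are built from maximal blocks of contiguous columns with
an identical set of gapped strains. Staggered gap boundaries split into
minimal identically-bounded blocks with a warning; two independently
planted adjacent indels are likewise reported as separate characters, which
is the only reading available from the alignment alone. Diagnostics are
computed among focal species only; outgroups are excluded.

## Distances, trees and monophyly

The K2P distance uses pairwise deletion: per pair, every column where
either sequence is not a plain A/C/G/T (gap, `?`, or ambiguity code) is
removed, and over the $n$ surviving columns with transition proportion $P$
and transversion proportion $Q$,

$$ d = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big]. $$

Treating ambiguity codes as missing mirrors common distance-software
behaviour; it is a documented choice, not something the data dictate. When
$1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is reported as saturated (an
error naming the pair) rather than silently NaN.

Neighbor-Joining follows the Saitou–Nei agglomeration on the Q-criterion
with two determinism rules: ties are broken toward the lexicographically
smallest label pair (each cluster carries the smallest leaf label it
contains), and a negative pendant estimate is clamped to zero with the
deficit moved to its sister branch so the joined pair's path length is
preserved. Determinism matters because bootstrap supports are defined
against the full-data topology: supports are the percentage of
column-resampled replicates whose NJ tree contains the same bipartition,
mapped onto the original tree (not onto a consensus), and replicates with
an undefined distance are redrawn and counted. One consequence of the
deterministic tie-break is that a completely uninformative alignment yields
the *same* arbitrary resolution in every replicate, so such edges can show
high support; the run log and the effective-site diagnostics, not the
support value alone, flag that situation.

Monophyly of a strain set on the rooted tree is exact set equality with
some node's descendant leaves (singletons pass trivially); rooting requires
the outgroup to be separable by a single edge. Across loci, a lightweight
split-concordance summary reports the fraction of locus trees containing
each species' clade — deliberately *not* a Bayesian concordance factor; a
tree whose tip set does not cover the clade counts against concordance.

## Concatenation and dating

Loci are concatenated over the strains shared by all loci (intersection
mode, the default) or over the union with `?`-padding; the real study had
unequal strain panels across loci and does not record which convention was
used, so both are provided and neither is asserted as "the" published one.
Partitions are recorded as 1-based inclusive column ranges tiling the
supermatrix.

Node ages come from **mean-path-length (MPL) ultrametricization**: the
height of a node is the mean path length to its descendant tips, with a
top-down clamp enforcing parent ≥ child (clamps are counted and logged).
A single calibration node — by default the outgroup pair, assigned
5.4 Mya, the conventional *D. melanogaster*–*D. simulans* split age —
rescales heights linearly into Mya. MPL is the simplest defensible clock
estimator over an NJ tree; it is a stand-in for whatever dating heuristic
produced the published figures, which is not recorded. It is
scale-equivariant (multiplying all branch lengths by a constant leaves
ages unchanged), which the tests assert.

## What the generator emulates — and what it does not

`default_lini_scenario()` encodes the study conditions:

| parameter | default | why |
|---|---|---|
| focal strain counts | 7 / 4 / 2 (*lini*/*ohnishii*/*ogumai*) | the study's sampling design |
| deepest focal divergence | 2.23 Mya | published estimate for the clade's oldest split |
| *D. ogumai* split | 1.42 Mya | published estimate |
| *D. lini*–*D. ohnishii* split | 0.17 Mya | published estimate |
| outgroup (calibration) pair | 5.4 Mya | melanogaster–simulans calibration age |
| tree root | 10 Mya | order-of-magnitude subgroup split; only relative depths matter downstream |
| rate | 0.1/5.4 ≈ 0.0185 subs/site/My | makes the calibration clade ~0.1 substitutions/site root-to-tip, a realistic mtDNA-scale depth |
| kappa | 4 | typical insect mtDNA transition bias |
| within-species depth | 0.25 My | of the same order as the youngest split — see below |
| loci | ND2 926, COI-COII 842, ITS 674 bp | published alignment widths (total 2442) |

Three structural choices deserve explanation:

* **Within-species genealogies are stars at a fixed depth**, not
  coalescents. A star is the simplest structure that produces shared
  polymorphism, and making its depth (0.25 My) *exceed* the youngest
  species split (0.17 My) places the strains of *D. lini* and
  *D. ohnishii* in one common star on the ancestral lineage — incomplete
  lineage sorting by construction. This is why, in simulation as in the
  real data, the two youngest species intermingle on every locus tree and
  yield no diagnostics, while *D. ogumai*, with ~1.2 My of private
  history, is monophyletic and diagnosable.
* **One *D. lini* lineage is basal at 2.23 Mya.** With only three focal
  species attached star-wise, the clade's deepest node would coincide with
  the *D. ogumai* split and the three published node ages could not all be
  planted. The real data themselves show a *D. lini* strain branching
  first within the clade with high support, so the default scenario gives
  *D. lini* a one-strain basal population: the deepest focal node (2.23)
  and the *D. ogumai* split (1.42) become distinct, plantable nodes, and
  *D. lini* is non-monophyletic by construction, as observed.
* **Indels are planted by gap-masking** a block of the simulated matrix
  (non-carriers become `-`) rather than inserting columns, so locus widths
  equal their nominal values exactly. The 14-bp ITS block is polymorphic in
  *D. ohnishii* (each strain deleted independently with probability 0.5)
  and a 1-bp insertion is private to *D. ogumai*, mirroring the two indel
  characters of the real ITS table.

Sequence evolution is plain K80: uniform root, independent sites,
transition probabilities in closed form per branch. No rate heterogeneity
across sites, no codon structure, no base-composition bias, no
recombination, selection or migration. Passing the recovery tests therefore
shows that the pipeline's estimators are consistent and approximately
unbiased *under their own model assumptions at realistic depths and sizes*;
it does not show robustness to the model violations real mitochondrial and
ribosomal data carry.

## Numerical and procedural details

* All randomness flows through explicit integer seeds; per-locus and
  per-stage seeds are derived deterministically from the top-level seed and
  kept below 2^31. Identical (scenario, seed) reproduce datasets
  bit-exactly; identical (config, seed) reproduce pipeline outputs
  byte-identically.
* Distance-matrix asymmetry beyond 1e-9 is a contract violation; Q-matrix
  ties within 1e-12 are treated as exact ties.
* `-` (alignment gap) and `?` (fully missing) are distinct: gaps
  participate in indel coding, `?` never does; both are removed by pairwise
  deletion.
* Columns touched by gaps among the focal strains are excluded from
  substitution-state collapse — their information is carried by the indel
  characters instead.
* The curated character tables ship as TSVs with a fixed dialect
  (`#locus` / `#ref` / `#species name N [verdict]` metadata, then
  `position  region  kind  <species...>`); readers and writers round-trip
  bit-exactly on canonical form, and an em-dash or `deletion` is accepted
  for indel absence on input.
* Site positions are 1-based reference coordinates (column + offset − 1),
  with per-locus reference systems: ND2 numbered on a *D. obscura*
  reference starting at site 34, COI-COII on *D. yakuba* as two ranges
  (COI 1407–1536, COII 1–639), ITS on the *D. ogumai* sequence.

## Problem sizes

The bundled studies use 20 seeded replicates of the 2442-site, 15-strain
default scenario for age recovery (reported as the mean over replicates,
with planted values 2.23 and 1.42 Mya), 30 replicates for the
diagnosability asymmetry, and bootstrap defaults of B = 1000 for final
trees (the analysis scripts use B = 200; tests use small B since support
percentages, not their precision, are under test). These sizes keep every
check cheap on a single CPU while leaving Monte-Carlo error well inside
the tolerances asserted.

## Known limitations

* MPL dating has no confidence intervals and no rate-smoothing; it will be
  biased when lineage-specific rates differ systematically.
* The star-within-species model cannot produce deep coalescent variance
  within *D. ogumai* or the outgroups; recovery tolerances would need
  widening under a true multispecies coalescent.
* The split-concordance summary is descriptive, not a posterior
  concordance factor.
* Diagnostics are single-site ("pure simple"); compound diagnostics and
  private-but-polymorphic characters are out of scope.
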