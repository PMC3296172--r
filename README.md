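# barcodelim

Species-delimitation toolkit for sibling species complexes, built around
the *Drosophila lini* clade (*D. lini*, *D. ohnishii*, *D. ogumai*): three
species that are nearly indistinguishable morphologically and only
partially reproductively isolated. The package implements, as one tested
pipeline, the three analyses such data call for:

1. **Character-based DNA barcoding** — collapse strains to per-species
   state sets (IUPAC codes for within-species polymorphism, coded indel
   characters for gaps) and call *pure simple diagnostics*: states fixed in
   one focal species and absent from all others at the homologous site.
2. **Phylogeny-based delimitation** — Kimura 2-parameter distances with
   pairwise deletion,
   d = −½·ln[(1 − 2P − Q)·√(1 − 2Q)]
   (P, Q = transition and transversion proportions), deterministic
   Neighbor-Joining, nonparametric bootstrap supports mapped onto the
   full-data topology, outgroup rooting, per-species monophyly tests, and a
   per-locus split-concordance summary.
3. **Calibrated divergence dating** — concatenation of the loci into a
   2442-bp supermatrix, mean-path-length ultrametricization of the NJ tree,
   and linear scaling at a single calibration node (default: the
   *D. melanogaster*–*D. simulans* split, 5.4 Mya).

A fully seeded synthetic-data module generates multilocus alignments with
the structure that makes this problem hard — within-species polymorphism,
incomplete lineage sorting between the two youngest species, a basal
divergent *D. lini* lineage, and a polymorphic 14-bp indel — together with
truth records for every downstream check. Curated per-species
character-state tables for the real ND2, COI-COII and ITS data ship as
plain-text fixtures under `inst/extdata/`.

See `vignettes/barcodelim-methods.Rmd` for the model, parameter defaults
and design decisions.

## Worked example

Diagnostics from the curated ND2 character-state table:

```r
library(barcodelim)
t3 <- read_character_table(system.file("extdata", "nd2_states.tsv",
                                       package = "barcodelim"))
nrow(find_informative_sites(t3))
#> [1] 20
calls <- call_pure_diagnostics(t3)
subset(calls, species == "D. ogumai")$position
#>  [1] 155 342 411 434 543 781 796 895 900 934 954
sum(calls$species != "D. ogumai")
#> [1] 0
```

Twenty sites vary among the 13 focal strains; eleven of them carry a state
fixed in *D. ogumai* and absent from its siblings, so *D. ogumai* is
identifiable from ND2 alone — while *D. lini* and *D. ohnishii*, which
separated only ~0.17 Mya, have no diagnostic at all.

The same asymmetry emerges from simulated data. One seeded replicate of the
default scenario, through the whole pipeline:

```r
r <- run_recovery_replicate(5)
r$monophyletic
#>      D. lini  D. ohnishii    D. ogumai
#>        FALSE        FALSE         TRUE
r$n_diagnostics
#>      D. lini  D. ohnishii    D. ogumai
#>            0            0           62
r$ages_est
#>     focal_root second_deepest
#>       1.875283       1.212404
```

The deep-split species is monophyletic and richly diagnosable; the young
pair intermingles with zero diagnostics. The two age estimates target the
planted node ages (2.23 and 1.42 Mya); averaged over 20 replicates they
recover them to within ~2% (`analysis/04_dating.R` prints the table).

The `analysis/` directory holds the numbered study scripts —
`01_simulate.R` (write the default dataset), `02_diagnostics.R` (curated
tables + simulated data), `03_trees.R` (per-locus NJ/bootstrap/monophyly,
concordance), `04_dating.R` (supermatrix dating and the 20-replicate
recovery study) — each writing its tables under `results/`.

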