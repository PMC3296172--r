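# Seeded multilocus sequence generator.
#
# The generator draws a strain-level genealogy from a dated species tree
# (tips may be populations mapped to species, so a species can carry a
# divergent basal lineage), evolves sequences along it under the
# two-parameter (kappa) substitution process, and optionally converts a block
# of columns into a (possibly polymorphic) indel. Within-species genealogies
# are stars at a fixed depth; letting that depth exceed a very recent species
# split makes the strains of the two young species coalesce on the shared
# ancestral lineage, which is the incomplete-lineage-sorting structure the
# delimitation analysis is meant to be challenged with.

#' Construct a simulation scenario
#'
#' @param species_tree rooted ultrametric `phylo` whose edge lengths are in
#'   Mya; tip labels are population labels.
#' @param tip_species named character vector mapping each species-tree tip to
#'   a species label (several tips may share a species).
#' @param strains_per_species named integer vector: strains sampled per tip.
#' @param focal_species species subject to delimitation.
#' @param outgroup_species species used for rooting/calibration.
#' @param rate substitution rate, substitutions/site/My (> 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param within_species_depth star depth of within-population genealogies,
#'   Mya; must be smaller than the root age.
#' @param loci list of locus descriptors: `name`, `length`, optional
#'   `ref_offset`, `ref_name`, `regions` (see [new_alignment()]).
#' @param indels optional list of indel specs: `locus`, `start`, `length`,
#'   `carriers` (species whose strains keep the inserted bases),
#'   `polymorphic_in` (species in which presence is polymorphic, or `NULL`),
#'   `frequency` (per-strain deletion probability in the polymorphic
#'   species, in (0,1)).
#' @param seed integer seed; the whole dataset is reproducible bit-exactly
#'   from (scenario, seed).
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(species_tree, tip_species, strains_per_species,
                         focal_species, outgroup_species, rate, kappa,
                         within_species_depth, loci, indels = list(),
                         seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"))
  if (rate <= 0 || kappa <= 0)
    bd_stop("bd_contract_violation", "rate and kappa must be > 0")
  if (!setequal(names(tip_species), species_tree$tip.label) ||
      !setequal(names(strains_per_species), species_tree$tip.label))
    bd_stop("bd_contract_violation",
            "tip_species and strains_per_species must cover the tree tips")
  if (any(strains_per_species < 1L))
    bd_stop("bd_contract_violation", "each population needs >= 1 strain")
  depths <- ape::node.depth.edgelength(species_tree)
  root_age <- max(depths)
  if (max(abs(depths[seq_along(species_tree$tip.label)] - root_age)) > 1e-8)
    bd_stop("bd_contract_violation", "species tree must be ultrametric")
  if (within_species_depth < 0 || within_species_depth >= root_age)
    bd_stop("bd_scenario_error",
            "within_species_depth must lie in [0, root age)")
  for (lc in loci)
    if (lc$length < 1L)
      bd_stop("bd_contract_violation", "locus lengths must be >= 1")
  for (id in indels) {
    if (!id$locus %in% vapply(loci, `[[`, "", "name"))
      bd_stop("bd_scenario_error", "indel locus '%s' not simulated", id$locus)
    if (!is.null(id$polymorphic_in) &&
        (id$frequency <= 0 || id$frequency >= 1))
      bd_stop("bd_contract_violation",
              "polymorphic indel frequency must be in (0,1)")
  }
  structure(list(species_tree = species_tree, tip_species = tip_species,
                 strains_per_species = strains_per_species,
                 focal_species = focal_species,
                 outgroup_species = outgroup_species, rate = rate,
                 kappa = kappa, within_species_depth = within_species_depth,
                 loci = loci, indels = indels, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Default Drosophila lini-clade scenario
#'
#' Three focal sibling species nested among a calibrated outgroup pair
#' (split 5.4 Mya), with node ages 2.23 (deepest focal divergence: a basal
#' *D. lini* population), 1.42 (*D. ogumai* split) and 0.17 Mya (the
#' *D. lini* / *D. ohnishii* split, shallower than the 0.25-My within-species
#' star depth, so the two youngest species share ancestral polymorphism).
#' Strain counts are 7/4/2 for *D. lini*/*D. ohnishii*/*D. ogumai*; the three
#' loci are ND2 (926 bp), COI-COII (842 bp) and ITS (674 bp, carrying a 14-bp
#' indel polymorphic in *D. ohnishii* and a 1-bp insertion private to
#' *D. ogumai*). The default rate, 0.1/5.4 substitutions/site/My, makes the
#' calibration-clade root-to-tip depth ~0.1 substitutions/site.
#'
#' @param seed integer seed.
#' @return A [sim_scenario()].
#' @export
default_lini_scenario <- function(seed = 1L) {
  tree <- read_newick(paste0(
    "((lini_basal:2.23,(ogumai:1.42,(lini_main:0.17,ohnishii:0.17):1.25)",
    ":0.81):7.77,(mel:5.4,sim:5.4):4.6);"))
  tip_species <- c(lini_basal = "D. lini", lini_main = "D. lini",
                   ohnishii = "D. ohnishii", ogumai = "D. ogumai",
                   mel = "D. melanogaster", sim = "D. simulans")
  strains <- c(lini_basal = 1L, lini_main = 6L, ohnishii = 4L, ogumai = 2L,
               mel = 1L, sim = 1L)
  loci <- list(
    list(name = "ND2", length = 926L, ref_offset = 34L,
         ref_name = "D. obscura"),
    list(name = "COI-COII", length = 842L, ref_offset = 1L,
         ref_name = "D. yakuba",
         regions = data.frame(region = c("COI", "COII"),
                              start_col = c(1L, 131L),
                              end_col = c(130L, 842L),
                              ref_start = c(1407L, 1L))),
    list(name = "ITS", length = 674L, ref_offset = 1L,
         ref_name = "D. ogumai"))
  indels <- list(
    list(locus = "ITS", start = 312L, length = 14L,
         carriers = c("D. lini", "D. ohnishii", "D. ogumai"),
         polymorphic_in = "D. ohnishii", frequency = 0.5),
    list(locus = "ITS", start = 326L, length = 1L,
         carriers = "D. ogumai", polymorphic_in = NULL, frequency = NULL))
  sim_scenario(species_tree = tree, tip_species = tip_species,
               strains_per_species = strains,
               focal_species = c("D. lini", "D. ohnishii", "D. ogumai"),
               outgroup_species = c("D. melanogaster", "D. simulans"),
               rate = 0.1 / 5.4, kappa = 4, within_species_depth = 0.25,
               loci = loci, indels = indels, seed = seed)
}

#' Strain-level genealogy implied by a scenario
#'
#' Each population contributes a star of strains attached at
#' `within_species_depth`; when that depth exceeds a node on the population's
#' root-ward path, the star sits on the ancestral lineage (shared ancestral
#' polymorphism between the populations below). Built deterministically from
#' the matrix of pairwise strain divergence times.
#'
#' @param scenario a `sim_scenario`.
#' @return Rooted ultrametric `phylo` over strain ids (`<population>_<k>`)
#'   with edge lengths in Mya, plus attribute `strain_species`.
#' @export
simulate_strain_tree <- function(scenario) {
  tr <- scenario$species_tree
  pops <- tr$tip.label
  depths <- ape::node.depth.edgelength(tr)
  root_age <- max(depths)
  ages <- root_age - depths   # node ages, tips 0
  mr <- ape::mrca(tr)
  w <- scenario$within_species_depth
  strains <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(scenario$strains_per_species[[p]]))))
  pop_of <- rep(pops, scenario$strains_per_species[pops])
  n <- length(strains)
  tmat <- matrix(0, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    t_pq <- if (pop_of[i] == pop_of[j]) 0 else ages[mr[pop_of[i], pop_of[j]]]
    tmat[i, j] <- tmat[j, i] <- max(t_pq, w)
  }
  phy <- ape::as.phylo(stats::hclust(stats::as.dist(2 * tmat),
                                     method = "average"))
  sp <- stats::setNames(scenario$tip_species[pop_of], strains)
  attr(phy, "strain_species") <- sp
  phy
}

# K80 transition probabilities at branch length d (expected subs/site):
# p_ts transition, p_tv EACH transversion.
k80_probs <- function(d, kappa) {
  b4 <- exp(-4 * d / (kappa + 2))
  ab2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  list(ts = 0.25 + 0.25 * b4 - 0.5 * ab2, tv = 0.25 - 0.25 * b4)
}

#' Simulate sequences along a tree under the K80 model
#'
#' The root sequence is uniform over `{A,C,G,T}`; each site evolves
#' independently along each branch under the two-parameter process with
#' transition/transversion rate ratio `kappa` and branch lengths in expected
#' substitutions/site.
#'
#' @param strain_tree rooted `phylo`, edge lengths in substitutions/site.
#' @param locus_length number of sites.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @param locus,ref_offset,ref_name,regions metadata passed to
#'   [new_alignment()].
#' @return A `dna_alignment` with attribute `site_changes` (number of
#'   observed state changes per site over all branches).
#' @export
simulate_sequences <- function(strain_tree, locus_length, kappa, seed,
                               locus = "locus", ref_offset = 1L,
                               ref_name = locus, regions = NULL) {
  ntip <- length(strain_tree$tip.label)
  nn <- ntip + strain_tree$Nnode
  L <- as.integer(locus_length)
  ts_partner <- c(3L, 4L, 1L, 2L)            # A<->G, C<->T
  tv_first <- c(2L, 1L, 2L, 1L)
  tv_second <- c(4L, 3L, 4L, 3L)
  nuc <- c("A", "C", "G", "T")
  seqs <- matrix(0L, nn, L)
  changes <- integer(L)
  with_seed(seed, {
    root <- ntip + 1L
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    pre <- ape::reorder.phylo(strain_tree, "cladewise")
    for (k in seq_len(nrow(pre$edge))) {
      p <- pre$edge[k, 1L]; ch <- pre$edge[k, 2L]
      pr <- k80_probs(pre$edge.length[k], kappa)
      parent <- seqs[p, ]
      u <- stats::runif(L)
      child <- parent
      is_ts <- u < pr$ts
      is_tv <- !is_ts & u < pr$ts + 2 * pr$tv
      child[is_ts] <- ts_partner[parent[is_ts]]
      if (any(is_tv)) {
        pick2 <- stats::runif(sum(is_tv)) < 0.5
        tv_to <- ifelse(pick2, tv_second[parent[is_tv]],
                        tv_first[parent[is_tv]])
        child[is_tv] <- tv_to
      }
      changes <- changes + (child != parent)
      seqs[ch, ] <- child
    }
  })
  mat <- matrix(nuc[seqs[seq_len(ntip), ]], ntip, L,
                dimnames = list(strain_tree$tip.label, NULL))
  aln <- new_alignment(mat, locus = locus, ref_offset = ref_offset,
                       ref_name = ref_name, regions = regions)
  attr(aln, "site_changes") <- changes
  aln
}

#' Convert a column block into a (possibly polymorphic) indel
#'
#' Strains of carrier species keep their simulated bases over the block;
#' all other strains get alignment gaps. Within the designated polymorphic
#' species each strain is gapped independently with the given frequency.
#' Alignment width is unchanged, so locus lengths match their nominal values.
#'
#' @param alignment a `dna_alignment`.
#' @param indel_spec list with `start`, `length`, `carriers`,
#'   `polymorphic_in`, `frequency` (see [sim_scenario()]).
#' @param partition a `species_partition` mapping the alignment's strains.
#' @param seed integer seed (used only for the polymorphic species).
#' @return The modified `dna_alignment`, with the planted region appended to
#'   attribute `indel_regions`.
#' @export
inject_indel <- function(alignment, indel_spec, partition, seed = 1L) {
  cols <- indel_spec$start:(indel_spec$start + indel_spec$length - 1L)
  if (max(cols) > ncol(alignment$mat))
    bd_stop("bd_scenario_error", "indel region exceeds locus length")
  prev <- attr(alignment, "indel_regions")
  for (rg in prev)
    if (length(intersect(cols, rg$cols)))
      bd_stop("bd_scenario_error",
              "indel region overlaps a previously injected indel")
  sp <- species_of(partition, rownames(alignment$mat))
  gapped <- !(sp %in% indel_spec$carriers)
  if (!is.null(indel_spec$polymorphic_in)) {
    poly <- which(sp == indel_spec$polymorphic_in)
    del <- with_seed(seed,
                     stats::runif(length(poly)) < indel_spec$frequency)
    gapped[poly[del]] <- TRUE
  }
  alignment$mat[gapped, cols] <- "-"
  attr(alignment, "indel_regions") <-
    c(prev, list(list(cols = cols, gapped = rownames(alignment$mat)[gapped])))
  alignment
}

#' Simulate a full multilocus dataset with truth records
#'
#' @param scenario a `sim_scenario`.
#' @return Object of class `sim_dataset`: `alignments` (named list),
#'   `partition` (a `species_partition`), `strain_tree` (Mya),
#'   `truth` (species node ages, per-locus seeds, planted indels, per-site
#'   change counts) and the `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  strain_tree <- simulate_strain_tree(scenario)
  sp <- attr(strain_tree, "strain_species")
  mapping <- data.frame(strain_id = names(sp), species = unname(sp),
                        role = ifelse(sp %in% scenario$outgroup_species,
                                      "outgroup", "focal"))
  partition <- species_partition(mapping)
  subs_tree <- strain_tree
  subs_tree$edge.length <- strain_tree$edge.length * scenario$rate
  nloci <- length(scenario$loci)
  locus_seeds <- vapply(seq_len(nloci), function(i)
    derive_seed(scenario$seed, i), 0L)
  indel_seeds <- vapply(seq_along(scenario$indels), function(i)
    derive_seed(scenario$seed, 1000L + i), 0L)
  alignments <- list()
  site_changes <- list()
  for (i in seq_len(nloci)) {
    lc <- scenario$loci[[i]]
    aln <- simulate_sequences(subs_tree, lc$length, scenario$kappa,
                              seed = locus_seeds[i], locus = lc$name,
                              ref_offset = lc$ref_offset %||% 1L,
                              ref_name = lc$ref_name %||% lc$name,
                              regions = lc$regions)
    site_changes[[lc$name]] <- attr(aln, "site_changes")
    alignments[[lc$name]] <- aln
  }
  for (i in seq_along(scenario$indels)) {
    id <- scenario$indels[[i]]
    alignments[[id$locus]] <- inject_indel(alignments[[id$locus]], id,
                                           partition,
                                           seed = indel_seeds[i])
  }
  focal_strains <- mapping$strain_id[mapping$role == "focal"]
  depths <- ape::node.depth.edgelength(strain_tree)
  ages <- max(depths) - depths
  deep <- ape::getMRCA(strain_tree, focal_strains)
  truth <- list(
    species_tree = scenario$species_tree,
    focal_strains = focal_strains,
    age_focal_root = ages[deep],
    locus_seeds = locus_seeds,
    indels = lapply(alignments, attr, "indel_regions"),
    site_changes = site_changes)
  structure(list(scenario = scenario, alignments = alignments,
                 partition = partition, strain_tree = strain_tree,
                 truth = truth),
            class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Per-locus aligned FASTA, the species map TSV, the true strain tree
#' (Newick, Mya) and a truth TSV (planted node ages).
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(dataset$alignments))
    write_fasta_alignment(dataset$alignments[[nm]],
                          file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", nm),
                                                ".fasta")))
  write_species_map(dataset$partition, file.path(dir, "species_map.tsv"))
  writeLines(write_newick(dataset$strain_tree),
             file.path(dir, "strain_tree_true.nwk"))
  ages <- data.frame(node = "focal_root",
                     age_mya = dataset$truth$age_focal_root)
  utils::write.table(ages, file.path(dir, "truth_ages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
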