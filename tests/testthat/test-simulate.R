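# Synthetic multilocus data: strain genealogy, K80 sequence evolution,
# planted indels, and the default lini-clade scenario.

test_that("the default scenario encodes the study conditions", {
  sc <- default_lini_scenario(seed = 1)
  expect_equal(sum(vapply(sc$loci, `[[`, 0L, "length")), 2442L)
  expect_length(sc$focal_species, 3L)
  counts <- tapply(sc$strains_per_species,
                   sc$tip_species[names(sc$strains_per_species)], sum)
  expect_equal(counts[["D. lini"]], 7L)
  expect_equal(counts[["D. ohnishii"]], 4L)
  expect_equal(counts[["D. ogumai"]], 2L)
  # outgroup calibration pair splits at 5.4 Mya
  depths <- ape::node.depth.edgelength(sc$species_tree)
  ages <- max(depths) - depths
  expect_equal(unname(ages[ape::getMRCA(sc$species_tree,
                                        c("mel", "sim"))]), 5.4)
  expect_equal(unname(ages[ape::getMRCA(sc$species_tree,
                                        c("lini_basal", "ogumai"))]), 2.23)
  expect_equal(unname(ages[ape::getMRCA(sc$species_tree,
                                        c("ogumai", "ohnishii"))]), 1.42)
})

test_that("strain trees attach stars at the within-species depth", {
  sc <- default_lini_scenario(seed = 1)
  tt <- simulate_strain_tree(sc)
  sp <- attr(tt, "strain_species")
  focal <- names(sp)[sp %in% sc$focal_species]
  expect_length(focal, 13L)
  depths <- ape::node.depth.edgelength(tt)
  ages <- max(depths) - depths
  expect_equal(unname(ages[ape::getMRCA(tt, focal)]), 2.23)
  # ILS: lini_main and ohnishii strains coalesce at the star depth (0.25),
  # above their 0.17 species split
  mixed <- grep("^(lini_main|ohnishii)_", tt$tip.label, value = TRUE)
  expect_equal(unname(ages[ape::getMRCA(tt, mixed)]), 0.25)
  og <- grep("^ogumai_", tt$tip.label, value = TRUE)
  expect_equal(unname(ages[ape::getMRCA(tt, og)]), 0.25)

  sc0 <- sc
  sc0$within_species_depth <- 0
  tt0 <- simulate_strain_tree(sc0)
  d0 <- ape::cophenetic.phylo(tt0)
  expect_equal(unname(d0["ogumai_1", "ogumai_2"]), 0)

  expect_error(sim_scenario(sc$species_tree, sc$tip_species,
                            sc$strains_per_species, sc$focal_species,
                            sc$outgroup_species, sc$rate, sc$kappa,
                            within_species_depth = 11, loci = sc$loci),
               class = "bd_scenario_error")
  expect_error(sim_scenario(sc$species_tree, sc$tip_species,
                            sc$strains_per_species, sc$focal_species,
                            sc$outgroup_species, rate = -1, kappa = 2,
                            within_species_depth = 0.25, loci = sc$loci),
               class = "bd_contract_violation")
})

test_that("sequence evolution is K80-consistent and seed-reproducible", {
  # zero branch lengths: all sequences identical to the root draw
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln0 <- simulate_sequences(star, 50, kappa = 2, seed = 5)
  expect_equal(aln0$mat["a", ], aln0$mat["b", ])
  expect_equal(sum(attr(aln0, "site_changes")), 0L)

  # two tips at K2P distance ~0.17018: recovered within 3 SE at L = 1e5
  d_true <- 0.170181
  two <- ape::read.tree(text = sprintf("(x:%f,y:%f);", d_true / 2,
                                       d_true / 2))
  aln <- simulate_sequences(two, 1e5, kappa = 2, seed = 11)
  d_hat <- as.numeric(k2p_distance(aln$mat["x", ], aln$mat["y", ]))
  expect_lt(abs(d_hat - d_true), 3 * sqrt(d_true / 1e5) * 1.5)

  # very large kappa: transversions essentially vanish
  alnk <- simulate_sequences(two, 2e4, kappa = 1e6, seed = 12)
  code <- barcodelim:::pair_codes(alnk$mat["x", ], alnk$mat["y", ])
  expect_lt(sum(code == 3L) / 2e4, 0.001)
  expect_gt(sum(code == 2L), 0)

  a1 <- simulate_sequences(two, 1000, kappa = 2, seed = 77)
  a2 <- simulate_sequences(two, 1000, kappa = 2, seed = 77)
  expect_identical(a1$mat, a2$mat)
})

test_that("substitution-type frequencies match the kappa-implied law", {
  d <- 0.3
  kappa <- 4
  two <- ape::read.tree(text = sprintf("(x:%f,y:%f);", d / 2, d / 2))
  L <- 1e5
  aln <- simulate_sequences(two, L, kappa = kappa, seed = 21)
  code <- barcodelim:::pair_codes(aln$mat["x", ], aln$mat["y", ])
  obs <- c(sum(code == 1L), sum(code == 2L), sum(code == 3L))
  pr <- barcodelim:::k80_probs(d, kappa)  # tip-to-tip distance d
  expected_p <- c(1 - pr$ts - 2 * pr$tv, pr$ts, 2 * pr$tv)
  gof <- stats::chisq.test(obs, p = expected_p)
  expect_gt(gof$p.value, 0.01)
})

test_that("planted indels respect carriers, frequency and overlap rules", {
  sc <- default_lini_scenario(seed = 9)
  ds <- simulate_dataset(sc)
  its <- ds$alignments$ITS
  # non-carrier outgroups are gapped over the 14-bp block
  expect_true(all(its$mat[c("mel_1", "sim_1"), 312:325] == "-"))
  # ogumai-private single-column insertion: everyone else gapped
  expect_true(all(its$mat[setdiff(rownames(its$mat),
                                  c("ogumai_1", "ogumai_2")), 326] == "-"))
  expect_true(all(its$mat[c("ogumai_1", "ogumai_2"), 326] != "-"))

  tab <- suppressWarnings(code_indels(its, ds$partition))
  ind <- tab$sites[tab$sites$kind == "indel", ]
  expect_true(312L %in% ind$position)
  calls <- call_pure_diagnostics(tab)
  expect_true(any(calls$kind == "indel" & calls$species == "D. ogumai" &
                    calls$position == 326L))

  # deletion frequency honored in expectation across seeds
  frac <- vapply(1:200, function(s) {
    a <- inject_indel(ds$alignments$ND2,
                      list(start = 10L, length = 4L,
                           carriers = sc$focal_species,
                           polymorphic_in = "D. ohnishii", frequency = 0.5),
                      ds$partition, seed = s)
    mean(a$mat[grep("^ohnishii_", rownames(a$mat)), 10] == "-")
  }, 0)
  expect_equal(mean(frac), 0.5, tolerance = 0.06)

  # overlapping injections are a scenario error
  a1 <- inject_indel(ds$alignments$ND2,
                     list(start = 10L, length = 4L,
                          carriers = sc$focal_species,
                          polymorphic_in = NULL), ds$partition, seed = 1)
  expect_error(inject_indel(a1, list(start = 12L, length = 2L,
                                     carriers = sc$focal_species,
                                     polymorphic_in = NULL),
                            ds$partition, seed = 1),
               class = "bd_scenario_error")
})

test_that("datasets are bit-exact reproducible and write to plain text", {
  d1 <- simulate_dataset(default_lini_scenario(seed = 4))
  d2 <- simulate_dataset(default_lini_scenario(seed = 4))
  expect_identical(lapply(d1$alignments, `[[`, "mat"),
                   lapply(d2$alignments, `[[`, "mat"))
  expect_identical(write_newick(d1$strain_tree),
                   write_newick(d2$strain_tree))
  d3 <- simulate_dataset(default_lini_scenario(seed = 5))
  expect_false(identical(d1$alignments$ND2$mat, d3$alignments$ND2$mat))

  dir <- tempfile()
  write_dataset(d1, dir)
  aln <- read_fasta_alignment(file.path(dir, "ND2.fasta"), "ND2",
                              ref_offset = 34L)
  expect_equal(aln$mat, d1$alignments$ND2$mat)
  part <- read_species_map(file.path(dir, "species_map.tsv"))
  expect_setequal(part$focal_species, d1$partition$focal_species)
})

test_that("the deep species is diagnosable while the young pair is not", {
  # asymmetry of the default scenario, summarized over a batch of seeds
  res <- lapply(1:30, function(s) run_recovery_replicate(400 + s))
  og_ok <- vapply(res, function(r)
    r$monophyletic[["D. ogumai"]] && r$n_diagnostics[["D. ogumai"]] >= 1,
    TRUE)
  expect_gte(mean(og_ok), 0.95)
  young0 <- vapply(res, function(r)
    r$n_diagnostics[["D. lini"]] == 0 &&
      r$n_diagnostics[["D. ohnishii"]] == 0, TRUE)
  expect_gt(mean(young0), 0.5)
  young_para <- vapply(res, function(r)
    !r$monophyletic[["D. lini"]] && !r$monophyletic[["D. ohnishii"]], TRUE)
  expect_gt(mean(young_para), 0.5)
})
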