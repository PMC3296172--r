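# Character-based barcoding: species-state collapse, indel coding,
# informative sites and pure diagnostics.

three_sp_partition <- function() {
  partition_from(lini = paste0("l", 1:3), ohnishii = paste0("h", 1:2),
                 ogumai = paste0("g", 1:2))
}

test_that("collapse keeps variable columns, drops invariant ones, unions polymorphism", {
  # col1: fixed difference; col2: invariant; col3: within-species polymorphism
  aln <- aln_from(list(l1 = "TAA", l2 = "TAA", l3 = "TAA",
                       h1 = "TAA", h2 = "TAG",
                       g1 = "CAA", g2 = "CAA"))
  tab <- collapse_to_species_states(aln, three_sp_partition())
  expect_equal(tab$sites$position, c(1L, 3L))
  expect_equal(tab$sites$states[[1]],
               list(lini = "T", ohnishii = "T", ogumai = "C"))
  expect_equal(tab$sites$states[[2]]$ohnishii, c("A", "G"))
  expect_equal(tab$counts, c(lini = 3L, ohnishii = 2L, ogumai = 2L))

  # input ambiguity codes expand into the species union
  aln2 <- aln_from(list(l1 = "R", l2 = "A", l3 = "A",
                        h1 = "A", h2 = "A", g1 = "A", g2 = "A"))
  tab2 <- collapse_to_species_states(aln2, three_sp_partition())
  expect_equal(tab2$sites$states[[1]]$lini, c("A", "G"))

  # species with zero strains is a contract violation
  part_extra <- species_partition(rbind(
    three_sp_partition()$mapping,
    data.frame(strain_id = "z1", species = "ghost", role = "focal")))
  expect_error(collapse_to_species_states(aln, part_extra),
               class = "bd_contract_violation")
})

test_that("indel coding builds presence/absence characters per gap block", {
  gap14 <- strrep("-", 14)
  ins14 <- strrep("TA", 7)
  aln <- aln_from(list(
    l1 = paste0("AA", ins14, "C"), l2 = paste0("AA", ins14, "C"),
    l3 = paste0("AA", ins14, "C"),
    h1 = paste0("AA", ins14, "C"), h2 = paste0("AA", gap14, "C"),
    g1 = paste0("AA", ins14, "C"), g2 = paste0("AA", ins14, "C")))
  tab <- code_indels(aln, three_sp_partition())
  ind <- tab$sites[tab$sites$kind == "indel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$position, 3L)
  expect_equal(ind$states[[1]]$lini, paste0("present:", ins14))
  expect_setequal(ind$states[[1]]$ohnishii,
                  c(paste0("present:", ins14), "absent"))

  # single inserted column private to one species: length-1 indel
  aln1 <- aln_from(list(l1 = "A-A", l2 = "A-A", l3 = "A-A",
                        h1 = "A-A", h2 = "A-A",
                        g1 = "ATA", g2 = "ATA"))
  tab1 <- code_indels(aln1, three_sp_partition())
  expect_equal(tab1$sites$kind, "indel")
  expect_equal(tab1$sites$states[[1]]$ogumai, "present:T")
  expect_equal(tab1$sites$states[[1]]$lini, "absent")

  # no gaps -> no indel records
  aln0 <- aln_from(list(l1 = "AC", l2 = "AC", l3 = "AC", h1 = "AC",
                        h2 = "AC", g1 = "AC", g2 = "AC"))
  expect_equal(nrow(code_indels(aln0, three_sp_partition())$sites), 0L)
})

test_that("staggered gap runs split into identically-bounded blocks with a warning", {
  aln <- aln_from(list(l1 = "A--AA", l2 = "AAAAA", l3 = "AAAAA",
                       h1 = "AA--A", h2 = "AAAAA",
                       g1 = "AAAAA", g2 = "AAAAA"))
  w <- capture_warnings(tab <- code_indels(aln, three_sp_partition()))
  expect_true(any(grepl("staggered", w)))
  ind <- tab$sites[tab$sites$kind == "indel", ]
  expect_equal(ind$position, c(2L, 3L, 4L))
})

test_that("informative sites include within-species-only polymorphism", {
  sites <- data.frame(position = c(1L, 2L, 3L), region = "X",
                      kind = "substitution")
  sites$states <- list(list(a = "T", b = "T", c = "C"),
                       list(a = "A", b = c("A", "G"), c = "A"),
                       list(a = "A", b = "A", c = "A"))
  tb <- char_table("X", sites, counts = c(a = 2L, b = 2L, c = 2L))
  expect_equal(find_informative_sites(tb)$position, c(1L, 2L))
})

test_that("pure diagnostics require fixation in one species and absence in the rest", {
  mk <- function(a, b, c) {
    sites <- data.frame(position = 1L, region = "X", kind = "substitution")
    sites$states <- list(list(a = a, b = b, c = c))
    char_table("X", sites, counts = c(a = 2L, b = 2L, c = 2L))
  }
  expect_equal(call_pure_diagnostics(mk("T", "T", "C"))$species, "c")
  # candidate state occurs inside another species' polymorphism
  expect_equal(nrow(call_pure_diagnostics(mk(c("A", "G"), "A", "G"))), 0L)
  expect_equal(nrow(call_pure_diagnostics(mk(c("C", "G"), c("C", "G"),
                                             "G"))), 0L)
  # polymorphic candidate species is never diagnosed
  expect_equal(nrow(call_pure_diagnostics(mk("A", "A", c("A", "G")))), 0L)
  # indel states compare as present:<motif> vs absent
  sites <- data.frame(position = 9L, region = "X", kind = "indel")
  sites$states <- list(list(a = "absent", b = "absent", c = "present:T"))
  tb <- char_table("X", sites, counts = c(a = 2L, b = 2L, c = 2L))
  calls <- call_pure_diagnostics(tb)
  expect_equal(calls$state, "present:T")
  expect_equal(calls$kind, "indel")
})

test_that("diagnostic calls agree with a brute-force checker on random alignments", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    aln <- random_alignment(n, sample(10:30, 1), ambig = TRUE)
    ids <- rownames(aln$mat)
    k1 <- sample(2:(n - 2), 1)
    part <- partition_from(spA = ids[1:k1], spB = ids[(k1 + 1):n])
    tab <- collapse_to_species_states(aln, part)
    calls <- call_pure_diagnostics(tab)
    oracle <- brute_force_diagnostics(aln, part)
    got <- if (nrow(calls)) paste(calls$position, calls$species)
    else character()
    want <- if (!is.null(oracle)) paste(oracle$col, oracle$species)
    else character()
    expect_setequal(got, want)
  }
})

test_that("adding strains perturbs diagnostics monotonically", {
  aln <- aln_from(list(l1 = "TTA", l2 = "TTA", l3 = "TTA",
                       h1 = "TTA", h2 = "TTA",
                       g1 = "CTA", g2 = "CTA"))
  part <- three_sp_partition()
  base <- call_pure_diagnostics(collapse_to_species_states(aln, part))
  expect_equal(base$species, "ogumai")

  # another species gains a strain carrying the diagnostic state -> destroyed
  aln_hit <- aln_from(list(l1 = "TTA", l2 = "TTA", l3 = "TTA",
                           h1 = "TTA", h2 = "TTA", h3 = "CTA",
                           g1 = "CTA", g2 = "CTA"))
  part_hit <- partition_from(lini = paste0("l", 1:3),
                             ohnishii = paste0("h", 1:3),
                             ogumai = paste0("g", 1:2))
  expect_equal(nrow(call_pure_diagnostics(
    collapse_to_species_states(aln_hit, part_hit))), 0L)

  # strains carrying only already-present states never create new calls
  aln_dup <- aln_from(list(l1 = "TTA", l2 = "TTA", l3 = "TTA", l4 = "TTA",
                           h1 = "TTA", h2 = "TTA",
                           g1 = "CTA", g2 = "CTA"))
  part_dup <- partition_from(lini = paste0("l", 1:4),
                             ohnishii = paste0("h", 1:2),
                             ogumai = paste0("g", 1:2))
  dup <- call_pure_diagnostics(collapse_to_species_states(aln_dup, part_dup))
  expect_equal(paste(dup$position, dup$species),
               paste(base$position, base$species))
})

test_that("delimitation summaries count and total correctly", {
  t3 <- read_character_table(fixture("nd2_states.tsv"))
  t4 <- read_character_table(fixture("coicoii_states.tsv"))
  calls <- rbind(call_pure_diagnostics(t3), call_pure_diagnostics(t4))
  sm <- summarize_delimitation(
    list(ND2 = t3, `COI-COII` = t4), calls,
    monophyly = list(ND2 = t3$verdicts, `COI-COII` = t4$verdicts))
  expect_true(all(sm$n_diagnostics <= sm$n_informative_sites))
  og <- sm[sm$species == "D. ogumai", ]
  expect_equal(og$n_diagnostics[og$locus == "ND2"], 11L)
  expect_equal(og$n_diagnostics[og$locus == "total"], 16L)
  expect_equal(og$monophyletic[og$locus == "ND2"], "monophyletic")
  expect_equal(sum(sm$n_diagnostics[sm$species != "D. ogumai"]), 0L)

  # mismatched species sets across loci are rejected
  bad <- char_table("Z", data.frame(position = integer(),
                                    region = character(),
                                    kind = character(),
                                    states = I(list())),
                    counts = c(other = 1L))
  expect_error(summarize_delimitation(list(ND2 = t3, Z = bad), calls),
               class = "bd_validation_error")
})
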