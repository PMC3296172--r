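# Independent oracles and small fixture builders shared across tests.

fixture <- function(name) {
  system.file("extdata", name, package = "barcodelim", mustWork = TRUE)
}

# Alignment from named sequence strings.
aln_from <- function(seqs, locus = "L", ref_offset = 1L, ...) {
  mat <- do.call(rbind, strsplit(toupper(unlist(seqs)), ""))
  rownames(mat) <- names(seqs)
  new_alignment(mat, locus = locus, ref_offset = ref_offset, ...)
}

# Partition from species -> strain vectors; last group optionally outgroup.
partition_from <- function(..., outgroup = NULL) {
  groups <- list(...)
  df <- do.call(rbind, lapply(names(groups), function(s)
    data.frame(strain_id = groups[[s]], species = s, role = "focal")))
  if (!is.null(outgroup)) {
    df2 <- data.frame(strain_id = outgroup, species = "outsp",
                      role = "outgroup")
    df <- rbind(df, df2)
  }
  species_partition(df)
}

# Brute-force pure-diagnostic oracle working directly on the raw alignment:
# per column and species, the species' strains must share a single expanded
# state that no other focal strain carries. Returns data.frame(col, species).
brute_force_diagnostics <- function(alignment, partition) {
  expand <- function(ch) {
    if (ch == "?") c("A", "C", "G", "T") else iupac_to_set(ch)
  }
  strains <- rownames(alignment$mat)
  sp <- partition$mapping$species[match(strains,
                                        partition$mapping$strain_id)]
  keep <- sp %in% partition$focal_species
  mat <- alignment$mat[keep, , drop = FALSE]
  sp <- sp[keep]
  out <- NULL
  for (j in seq_len(ncol(mat))) {
    if (any(mat[, j] == "-")) next
    sets <- lapply(mat[, j], expand)
    for (s in unique(sp)) {
      own <- unique(unlist(sets[sp == s]))
      others <- unique(unlist(sets[sp != s]))
      if (length(own) == 1L && !(own %in% others))
        out <- rbind(out, data.frame(col = j, species = s))
    }
  }
  out
}

# Brute-force monophyly oracle: enumerate every node's descendant tip set.
brute_force_monophyletic <- function(phy, tips) {
  if (length(tips) == 1L) return(TRUE)
  ntip <- length(phy$tip.label)
  for (v in seq_len(ntip + phy$Nnode)) {
    set <- if (v <= ntip) phy$tip.label[v]
    else ape::extract.clade(phy, v)$tip.label
    if (setequal(set, tips)) return(TRUE)
  }
  FALSE
}

# Path-length metric of a tree (the additive distances NJ must recover).
path_metric <- function(phy) {
  m <- ape::cophenetic.phylo(phy)
  m[phy$tip.label, phy$tip.label]
}

# Mutationally related strains (so pairwise distances stay unsaturated).
related_alignment <- function(n_strains, n_sites, mut = 0.05) {
  base <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  mat <- t(vapply(seq_len(n_strains), function(i) {
    hit <- stats::runif(n_sites) < mut
    out <- base
    out[hit] <- vapply(base[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    out
  }, character(n_sites)))
  rownames(mat) <- sprintf("s%02d", seq_len(n_strains))
  new_alignment(mat, locus = "rel")
}

# Random alignment over ACGT plus optional ambiguity codes.
random_alignment <- function(n_strains, n_sites, ambig = FALSE) {
  alphabet <- c("A", "C", "G", "T",
                if (ambig) c("R", "Y", "S", "W", "K", "M", "?"))
  mat <- matrix(sample(alphabet, n_strains * n_sites, replace = TRUE,
                       prob = c(rep(10, 4), rep(1, length(alphabet) - 4))),
                n_strains, n_sites,
                dimnames = list(sprintf("s%02d", seq_len(n_strains)), NULL))
  new_alignment(mat, locus = "rand")
}
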