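# Character-based DNA barcoding: collapse strains to per-species state sets,
# code indel characters, list informative sites, and call pure simple
# diagnostics (states fixed in one species and absent from every other focal
# species at the homologous site).

expand_char <- function(ch) {
  if (ch == "?") c("A", "C", "G", "T") else iupac_to_set(ch)
}

# Species (ordered by first appearance among focal strains) and row indices.
focal_layout <- function(alignment, partition, focal_only) {
  strains <- rownames(alignment$mat)
  sp <- species_of(partition, strains)
  keep <- if (focal_only) sp %in% partition$focal_species else rep(TRUE,
                                                                   length(sp))
  if (!any(keep))
    bd_stop("bd_contract_violation", "no focal strains in alignment '%s'",
            alignment$locus)
  strains <- strains[keep]
  sp <- sp[keep]
  species <- unique(sp)
  missing <- setdiff(if (focal_only) partition$focal_species else species,
                     species)
  if (length(missing))
    bd_stop("bd_contract_violation",
            "species with zero strains in alignment '%s': %s",
            alignment$locus, paste(missing, collapse = ", "))
  list(strains = strains, species_of = sp, species = species,
       counts = stats::setNames(as.integer(table(sp)[species]), species))
}

#' Collapse an alignment to per-species character states
#'
#' For every alignment column that is variable among the retained strains,
#' records the union of the strains' (IUPAC-expanded) nucleotide states per
#' species; `?` contributes the full `{A,C,G,T}` set. Columns where every
#' strain carries one identical state are dropped, as are columns touched by
#' alignment gaps (those are handled as indel characters by [code_indels()]).
#'
#' @param alignment a `dna_alignment`.
#' @param partition a `species_partition` covering all alignment strains.
#' @param focal_only if `TRUE` (default) restrict to strains of focal species.
#' @return A [char_table()] of substitution sites.
#' @export
collapse_to_species_states <- function(alignment, partition,
                                       focal_only = TRUE) {
  lay <- focal_layout(alignment, partition, focal_only)
  mat <- alignment$mat[lay$strains, , drop = FALSE]
  gap_col <- colSums(mat == "-") > 0L
  sites <- list()
  positions <- integer()
  regions <- character()
  for (j in which(!gap_col)) {
    col <- mat[, j]
    sets <- lapply(col, expand_char)
    if (length(unique(unlist(sets))) == 1L) next  # invariant column
    st <- lapply(lay$species, function(s)
      sort(unique(unlist(sets[lay$species_of == s]))))
    names(st) <- lay$species
    ref <- col_to_ref(alignment, j)
    sites[[length(sites) + 1L]] <- st
    positions <- c(positions, ref$position)
    regions <- c(regions, ref$region)
  }
  df <- data.frame(position = positions, region = regions,
                   kind = rep("substitution", length(sites)))
  df$states <- sites
  char_table(locus = alignment$locus, sites = df, counts = lay$counts,
             ref = alignment$ref_name)
}

# Gap blocks: maximal runs of contiguous columns sharing an identical
# (nonempty) set of gapped strains. Staggered gaps (a strain's gap run
# spilling across adjacent blocks) are split into minimal identically-bounded
# blocks with a warning.
gap_blocks <- function(mat) {
  gap <- mat == "-"
  if (!any(gap)) return(list())
  pattern <- apply(gap, 2L, function(v) paste(which(v), collapse = ","))
  blocks <- list()
  j <- 1L
  while (j <= ncol(mat)) {
    if (pattern[j] == "") { j <- j + 1L; next }
    k <- j
    while (k < ncol(mat) && pattern[k + 1L] == pattern[j]) k <- k + 1L
    blocks[[length(blocks) + 1L]] <-
      list(start = j, end = k,
           gapped = as.integer(strsplit(pattern[j], ",")[[1L]]))
    j <- k + 1L
  }
  for (i in seq_along(blocks)[-1L]) {
    if (blocks[[i]]$start == blocks[[i - 1L]]$end + 1L &&
        length(intersect(blocks[[i]]$gapped, blocks[[i - 1L]]$gapped)))
      warning(sprintf("staggered gap boundaries near column %d split into separate indel blocks",
                      blocks[[i]]$start), call. = FALSE)
  }
  blocks
}

#' Code alignment gaps as indel characters
#'
#' Each maximal identically-bounded block of contiguous gap columns becomes
#' one indel character with per-strain states `present:<bases>` (the strain's
#' own ungapped sequence over the block, so presence with different motifs
#' counts as different states) or `absent`, collapsed to per-species state
#' sets. Blocks invariant across the retained strains are dropped.
#'
#' @inheritParams collapse_to_species_states
#' @param table optional [char_table()] (typically from
#'   [collapse_to_species_states()]) to append to.
#' @return A [char_table()] including the indel characters, ordered by
#'   position within region.
#' @export
code_indels <- function(alignment, partition, focal_only = TRUE,
                        table = NULL) {
  lay <- focal_layout(alignment, partition, focal_only)
  mat <- alignment$mat[lay$strains, , drop = FALSE]
  blocks <- gap_blocks(mat)
  sites <- list()
  positions <- integer()
  regions <- character()
  for (b in blocks) {
    cols <- b$start:b$end
    strain_state <- vapply(seq_len(nrow(mat)), function(i) {
      seg <- mat[i, cols]
      if (all(seg == "-")) "absent"
      else paste0("present:", paste(seg, collapse = ""))
    }, "")
    if (length(unique(strain_state)) == 1L) next
    st <- lapply(lay$species, function(s)
      sort(unique(strain_state[lay$species_of == s])))
    names(st) <- lay$species
    ref <- col_to_ref(alignment, b$start)
    sites[[length(sites) + 1L]] <- st
    positions <- c(positions, ref$position)
    regions <- c(regions, ref$region)
  }
  df <- data.frame(position = positions, region = regions,
                   kind = rep("indel", length(sites)))
  df$states <- sites
  indel_tab <- char_table(locus = alignment$locus, sites = df,
                          counts = lay$counts, ref = alignment$ref_name)
  if (is.null(table)) table <- collapse_to_species_states(alignment,
                                                          partition,
                                                          focal_only)
  merged <- rbind(table$sites, indel_tab$sites)
  ord <- order(match(merged$region, unique(merged$region)), merged$position)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  char_table(locus = table$locus, sites = merged, counts = table$counts,
             ref = table$ref, verdicts = table$verdicts)
}

#' List informative sites of a character-state table
#'
#' Informative here means variable among the focal strains — including sites
#' whose only variation is within-species polymorphism — not the stricter
#' parsimony-informative notion.
#'
#' @param table a [char_table()].
#' @return The subset of `table$sites` that is variable, ordered by position
#'   within region.
#' @export
find_informative_sites <- function(table) {
  if (nrow(table$sites) == 0L) return(table$sites)
  keep <- vapply(table$sites$states, function(st)
    length(unique(unlist(st))) > 1L || any(lengths(st) > 1L), TRUE)
  out <- table$sites[keep, , drop = FALSE]
  ord <- order(match(out$region, unique(out$region)), out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call pure simple diagnostic characters
#'
#' A species is diagnosed at a site iff its state set is a singleton `{x}`
#' and `x` is absent from the state sets of all other focal species there;
#' a species polymorphic at the site is never diagnosed. For indel
#' characters, `present:<motif>` and `absent` are the comparable states.
#'
#' @param table a [char_table()].
#' @param focal_species species among which diagnostics are sought; defaults
#'   to all species in the table.
#' @return data.frame with columns `locus`, `position`, `region`, `kind`,
#'   `species`, `state` (one row per diagnostic call).
#' @export
call_pure_diagnostics <- function(table, focal_species = NULL) {
  focal_species <- focal_species %||% names(table$counts)
  if (!all(focal_species %in% names(table$counts)))
    bd_stop("bd_validation_error", "table does not cover species: %s",
            paste(setdiff(focal_species, names(table$counts)), collapse = ", "))
  calls <- list()
  for (i in seq_len(nrow(table$sites))) {
    st <- table$sites$states[[i]][focal_species]
    for (s in focal_species) {
      if (length(st[[s]]) != 1L) next
      x <- st[[s]]
      others <- unlist(st[setdiff(focal_species, s)], use.names = FALSE)
      if (x %in% others) next
      calls[[length(calls) + 1L]] <-
        data.frame(locus = table$locus,
                   position = table$sites$position[i],
                   region = table$sites$region[i],
                   kind = table$sites$kind[i], species = s, state = x)
    }
  }
  if (length(calls) == 0L)
    return(data.frame(locus = character(), position = integer(),
                      region = character(), kind = character(),
                      species = character(), state = character()))
  do.call(rbind, calls)
}

#' Summarize delimitation evidence per locus and species
#'
#' @param tables named list of [char_table()] objects (one per locus), all
#'   covering the same species.
#' @param calls data.frame of diagnostic calls as returned by
#'   [call_pure_diagnostics()] (rows for all loci combined).
#' @param monophyly optional named list (locus -> named character vector of
#'   per-species verdicts); `untested` where absent.
#' @return data.frame with columns `locus`, `species`, `n_informative_sites`,
#'   `n_diagnostics`, `monophyletic`; plus grand-total rows (`locus = "total"`).
#' @export
summarize_delimitation <- function(tables, calls, monophyly = NULL) {
  species <- names(tables[[1L]]$counts)
  for (tb in tables)
    if (!setequal(names(tb$counts), species))
      bd_stop("bd_validation_error", "species sets differ across loci")
  rows <- list()
  for (locus in names(tables)) {
    info <- find_informative_sites(tables[[locus]])
    for (s in species) {
      nd <- sum(calls$locus == locus & calls$species == s)
      verdict <- monophyly[[locus]][s]
      rows[[length(rows) + 1L]] <-
        data.frame(locus = locus, species = s,
                   n_informative_sites = nrow(info), n_diagnostics = nd,
                   monophyletic = if (is.null(monophyly) || is.na(verdict))
                     "untested" else unname(verdict))
    }
  }
  out <- do.call(rbind, rows)
  totals <- stats::aggregate(cbind(n_informative_sites, n_diagnostics) ~
                               species, data = out, FUN = sum)
  totals <- data.frame(locus = "total", species = totals$species,
                       n_informative_sites = totals$n_informative_sites,
                       n_diagnostics = totals$n_diagnostics,
                       monophyletic = NA_character_)
  rbind(out, totals[match(species, totals$species), ])
}
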