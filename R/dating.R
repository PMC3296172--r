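# Multilocus concatenation and calibration-point divergence dating.
#
# Dating pipeline: NJ tree on the concatenated K2P distances, rooted on the
# outgroup, ultrametricized by the mean-path-length clock (each internal
# node's height is the average path length to its descendant tips, with a
# top-down clamp enforcing parent >= child), then linearly rescaled so one
# calibrated node takes its known age in Mya.

#' Concatenate per-locus alignments into a supermatrix
#'
#' @param alignments named list of `dna_alignment` objects (names = loci).
#' @param mode `"intersection"` (default) keeps only strains present in all
#'   loci, in the order of the first locus; `"pad"` keeps the union of
#'   strains, filling absent loci with `?` (fully missing).
#' @return Object of class `supermatrix`: `$alignment` (a `dna_alignment`)
#'   and `$partitions` (data.frame `locus`, `start`, `end`, 1-based
#'   inclusive column ranges tiling the matrix).
#' @export
concatenate_loci <- function(alignments, mode = c("intersection", "pad")) {
  mode <- match.arg(mode)
  if (length(alignments) == 0L)
    bd_stop("bd_contract_violation", "need at least one alignment")
  strain_sets <- lapply(alignments, function(a) rownames(a$mat))
  if (mode == "intersection") {
    shared <- Reduce(intersect, strain_sets)
    strains <- strain_sets[[1L]][strain_sets[[1L]] %in% shared]
    if (length(strains) == 0L)
      bd_stop("bd_validation_error", "no strain is present in every locus")
  } else {
    strains <- unique(unlist(strain_sets))
  }
  widths <- vapply(alignments, function(a) ncol(a$mat), 0L)
  blocks <- lapply(alignments, function(a) {
    m <- matrix("?", length(strains), ncol(a$mat),
                dimnames = list(strains, NULL))
    present <- intersect(strains, rownames(a$mat))
    m[present, ] <- a$mat[present, , drop = FALSE]
    m
  })
  ends <- cumsum(widths)
  partitions <- data.frame(locus = names(alignments),
                           start = ends - widths + 1L, end = ends,
                           row.names = NULL)
  aln <- new_alignment(do.call(cbind, blocks), locus = "concatenated",
                       ref_offset = 1L, ref_name = "supermatrix")
  structure(list(alignment = aln, partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d strains x %d sites; partitions: %s\n",
              nrow(x$alignment$mat), ncol(x$alignment$mat),
              paste(sprintf("%s %d-%d", x$partitions$locus,
                            x$partitions$start, x$partitions$end),
                    collapse = ", ")))
  invisible(x)
}

#' Write a supermatrix and its partition table
#' @param sm a `supermatrix`.
#' @param fasta,partitions output paths (FASTA; TSV `locus`,`start`,`end`).
#' @return `fasta`, invisibly.
#' @export
write_supermatrix <- function(sm, fasta, partitions) {
  write_fasta_alignment(sm$alignment, fasta)
  utils::write.table(sm$partitions, partitions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta)
}

#' Mean-path-length node heights of a rooted tree
#'
#' The height of node `v` is the mean path length from `v` to each of its
#' descendant tips; tips have height 0. A top-down pass clamps every child
#' to at most its parent's height (NJ branch lengths need not be clock-like);
#' the number of clamped nodes is reported as attribute `n_clamped`.
#'
#' @param rooted_tree rooted `phylo` with branch lengths.
#' @return Numeric vector of heights indexed by node number
#'   (`1..Ntip+Nnode`), with attribute `n_clamped`.
#' @export
ultrametricize <- function(rooted_tree) {
  if (!ape::is.rooted(rooted_tree))
    bd_stop("bd_contract_violation", "tree must be rooted")
  ntip <- length(rooted_tree$tip.label)
  nn <- ntip + rooted_tree$Nnode
  po <- ape::reorder.phylo(rooted_tree, "postorder")
  sums <- numeric(nn)   # sum over descendant tips of path length
  cnts <- integer(nn)
  cnts[seq_len(ntip)] <- 1L
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sums[p] <- sums[p] + sums[ch] + cnts[ch] * po$edge.length[k]
    cnts[p] <- cnts[p] + cnts[ch]
  }
  h <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), 0)
  h[seq_len(ntip)] <- 0
  # top-down clamp: parent height bounds child height
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  n_clamped <- 0L
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    if (h[ch] > h[p] + 1e-12) {
      h[ch] <- h[p]
      n_clamped <- n_clamped + 1L
    }
  }
  attr(h, "n_clamped") <- n_clamped
  h
}

#' Convert node heights to absolute ages via one calibration point
#'
#' Ages are heights linearly rescaled so the most recent common ancestor of
#' the calibration clade takes the calibration age; tips have age 0.
#'
#' @param rooted_tree rooted `phylo` the heights belong to.
#' @param heights node heights from [ultrametricize()].
#' @param clade strain labels whose MRCA is the calibrated node (>= 2).
#' @param age calibration age in Mya (default 5.4, the
#'   melanogaster-simulans split).
#' @return Object of class `dated_tree`: `$tree` (ultrametric `phylo` with
#'   edge lengths in Mya), `$ages` (per-node), `$calibration_node`, `$scale`.
#' @export
calibrate_ages <- function(rooted_tree, heights, clade, age = 5.4) {
  if (age <= 0) bd_stop("bd_contract_violation", "calibration age must be > 0")
  if (length(clade) < 2L)
    bd_stop("bd_contract_violation", "calibration clade needs >= 2 strains")
  node <- ape::getMRCA(rooted_tree, clade)
  if (heights[node] <= 0)
    bd_stop("bd_degenerate_calibration",
            "calibration MRCA has height 0; cannot scale")
  scale <- age / heights[node]
  ages <- heights * scale
  dated <- rooted_tree
  dated$edge.length <- ages[dated$edge[, 1L]] - ages[dated$edge[, 2L]]
  structure(list(tree = dated, ages = as.numeric(ages),
                 calibration_node = node, scale = scale),
            class = "dated_tree")
}

#' Age of the MRCA of a strain set on a dated tree
#' @param dated a `dated_tree`.
#' @param strains >= 2 tip labels.
#' @return Age in Mya.
#' @export
mrca_age <- function(dated, strains) {
  dated$ages[ape::getMRCA(dated$tree, strains)]
}

#' @export
print.dated_tree <- function(x, ...) {
  root <- length(x$tree$tip.label) + 1L
  cat(sprintf("<dated_tree> %d tips; root age %.3f Mya; calibration node %d (x%.4g)\n",
              length(x$tree$tip.label), x$ages[root], x$calibration_node,
              x$scale))
  invisible(x)
}

#' Concatenate, build the NJ tree and date it at one calibration node
#'
#' Convenience wrapper for the dating pipeline: supermatrix -> pairwise K2P
#' -> NJ -> outgroup rooting -> mean-path-length heights -> calibration.
#'
#' @param alignments named list of `dna_alignment` objects.
#' @param outgroup_strains tip labels used for rooting.
#' @param calibration_clade strain labels of the calibrated node's MRCA
#'   (defaults to the outgroup strains).
#' @param calibration_age age of the calibrated node in Mya.
#' @param mode concatenation mode, see [concatenate_loci()].
#' @return List: `supermatrix`, `tree` (rooted NJ), `dated` (a `dated_tree`).
#' @export
date_supermatrix <- function(alignments, outgroup_strains,
                             calibration_clade = outgroup_strains,
                             calibration_age = 5.4,
                             mode = "intersection") {
  sm <- concatenate_loci(alignments, mode = mode)
  dm <- k2p_distance_matrix(sm$alignment)
  tr <- root_with_outgroup(nj_tree(dm), outgroup_strains)
  h <- ultrametricize(tr)
  dated <- calibrate_ages(tr, h, clade = calibration_clade,
                          age = calibration_age)
  list(supermatrix = sm, tree = tr, dated = dated)
}
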