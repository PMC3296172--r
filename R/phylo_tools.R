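# Bipartition bookkeeping, bootstrap support, outgroup rooting, monophyly
# testing and per-locus split concordance.

# Canonical key of the leaf set below each edge: the side NOT containing the
# alphabetically first tip label, sorted and joined. Named by the child node
# of the edge.
bipartition_keys <- function(phy, internal_only = TRUE) {
  tips <- phy$tip.label
  ref <- sort(tips)[1L]
  ntip <- length(tips)
  desc <- descendant_sets(phy)
  nodes <- if (internal_only) (ntip + 1L):(ntip + phy$Nnode) else
    seq_len(ntip + phy$Nnode)
  keys <- character(0)
  for (v in nodes) {
    set <- desc[[v]]
    if (length(set) %in% c(0L, ntip)) next
    side <- if (ref %in% set) setdiff(tips, set) else set
    if (length(side) %in% c(0L, ntip)) next
    keys[as.character(v)] <- paste(sort(side), collapse = "\r")
  }
  keys
}

# Tip labels below every node (tips included), indexed by node number.
descendant_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(po)))
    sets[[po[k, 1L]]] <- c(sets[[po[k, 1L]]], sets[[po[k, 2L]]])
  sets
}

#' Bootstrap support for a Neighbor-Joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree per replicate, and maps onto each internal edge of the full-data NJ
#' tree the percentage of replicates containing the same bipartition.
#' Replicates in which any pairwise distance is undefined (no comparable
#' sites, or K2P saturation) are redrawn and counted.
#'
#' @param alignment a `dna_alignment`.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed for the column resampling.
#' @return The full-data NJ `phylo` with supports (0-100) in `node.label`,
#'   plus attributes `supports` (named by internal node) and `n_redrawn`.
#' @export
bootstrap_support <- function(alignment, B = 1000L, seed = 1L) {
  if (B < 1L) bd_stop("bd_contract_violation", "B must be >= 1")
  labels <- rownames(alignment$mat)
  codes <- pair_code_matrix(alignment$mat)
  full <- nj_tree(dist_from_codes(codes, labels))
  orig <- bipartition_keys(full)
  counts <- stats::setNames(numeric(length(orig)), names(orig))
  n_redrawn <- 0L
  L <- ncol(alignment$mat)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(L, L, replace = TRUE)
        rep_dm <- tryCatch(dist_from_codes(codes, labels, cols = idx),
                           barcodelim_error = function(e) NULL)
        if (!is.null(rep_dm)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * B)
          bd_stop("bd_validation_error",
                  "bootstrap replicates undefined too often; giving up")
      }
      rep_keys <- bipartition_keys(nj_tree(rep_dm))
      counts <- counts + (orig %in% rep_keys)
    }
  })
  supports <- 100 * counts / B
  ntip <- length(full$tip.label)
  lab <- rep("", full$Nnode)
  idx <- as.integer(names(orig)) - ntip
  lab[idx] <- sprintf("%g", supports)
  full$node.label <- lab
  attr(full, "supports") <- supports
  attr(full, "n_redrawn") <- n_redrawn
  full
}

#' Root a tree on its outgroup
#'
#' The outgroup must be separable from the rest by a single edge (a single
#' leaf always is). Node labels are treated as edge (support) labels while
#' re-rooting so bootstrap values stay attached to the correct splits.
#'
#' @param tree unrooted (or rooted) `phylo`.
#' @param outgroup_strains tip labels of the outgroup.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_strains) {
  missing <- setdiff(outgroup_strains, tree$tip.label)
  if (length(missing))
    bd_stop("bd_contract_violation", "outgroup strains not in tree: %s",
            paste(missing, collapse = ", "))
  if (length(outgroup_strains) > 1L &&
      length(outgroup_strains) < length(tree$tip.label) - 1L) {
    keys <- bipartition_keys(tree, internal_only = FALSE)
    out_key <- paste(sort(outgroup_strains), collapse = "\r")
    comp_key <- paste(sort(setdiff(tree$tip.label, outgroup_strains)),
                      collapse = "\r")
    if (!(out_key %in% keys || comp_key %in% keys))
      bd_stop("bd_rooting_error",
              "outgroup {%s} is not separated from the ingroup by one edge",
              paste(outgroup_strains, collapse = ","))
  }
  ape::root(tree, outgroup = outgroup_strains, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Test whether a strain set is monophyletic on a rooted tree
#'
#' True iff some node's descendant-leaf set equals the strain set exactly;
#' singletons are always monophyletic.
#'
#' @param rooted_tree rooted `phylo`.
#' @param strain_set nonempty subset of the tree's tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(rooted_tree, strain_set) {
  if (length(strain_set) == 0L)
    bd_stop("bd_contract_violation", "empty strain set")
  unknown <- setdiff(strain_set, rooted_tree$tip.label)
  if (length(unknown))
    bd_stop("bd_contract_violation", "strains not in tree: %s",
            paste(unknown, collapse = ", "))
  if (length(strain_set) == 1L) return(TRUE)
  ape::is.monophyletic(rooted_tree, tips = strain_set)
}

#' Fraction of locus trees containing a clade
#'
#' A lightweight per-locus split-concordance summary (not a Bayesian
#' concordance factor): the fraction of trees whose tip set covers the clade
#' and on which the clade is monophyletic. Trees missing clade members count
#' against concordance.
#'
#' @param per_locus_trees list of rooted `phylo` trees.
#' @param clade_of_interest strain labels defining the clade.
#' @return Fraction in `[0, 1]`.
#' @export
locus_concordance <- function(per_locus_trees, clade_of_interest) {
  if (length(per_locus_trees) == 0L)
    bd_stop("bd_contract_violation", "need at least one tree")
  hits <- vapply(per_locus_trees, function(tr) {
    all(clade_of_interest %in% tr$tip.label) &&
      is_monophyletic(tr, clade_of_interest)
  }, TRUE)
  mean(hits)
}
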