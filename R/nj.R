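# Neighbor-Joining (Saitou-Nei) with a deterministic tie-break and explicit
# handling of negative branch-length estimates: ties on the Q-criterion are
# resolved toward the lexicographically smallest label pair (clusters carry
# the smallest leaf label they contain), and a negative pendant estimate is
# clamped to zero with the deficit transferred to its sister branch so the
# joined pair's path length is preserved.

#' Neighbor-Joining tree from a distance matrix
#'
#' @param dm a `k2p_dist` or a labeled symmetric numeric matrix
#'   (>= 3 labels).
#' @return Unrooted `phylo` tree (binary up to the root trifurcation of the
#'   unrooted representation).
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "k2p_dist")) dm$d else dm
  if (!is.matrix(d) || is.null(rownames(d)))
    bd_stop("bd_contract_violation", "need a labeled distance matrix")
  if (nrow(d) < 3L)
    bd_stop("bd_contract_violation", "NJ needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9)
    bd_stop("bd_contract_violation", "distance matrix asymmetric beyond 1e-9")
  labels <- rownames(d)     # smallest leaf label of each live cluster
  reps <- rownames(d)       # Newick fragment of each live cluster
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 & upper.tri(q), arr.ind = TRUE)
    key <- apply(cand, 1L, function(ij)
      paste(sort(labels[ij]), collapse = "\r"))
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- d[i, j]; vi <- 0 }
    if (vj < 0) { vi <- d[i, j]; vj <- 0 }
    new_rep <- sprintf("(%s:%s,%s:%s)", reps[i], fmt(vi), reps[j], fmt(vj))
    new_lab <- min(labels[c(i, j)])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    labels <- c(labels[keep], new_lab)
    reps <- c(reps[keep], new_rep)
    rownames(d) <- colnames(d) <- labels
  }
  v1 <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  v2 <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  v3 <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", reps[1], fmt(v1), reps[2], fmt(v2),
                 reps[3], fmt(v3))
  read_newick(txt)
}
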