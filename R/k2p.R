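# Kimura 2-parameter distances with pairwise deletion.
#
# Pairwise deletion removes, per pair, every column where either sequence is
# anything but a plain A/C/G/T (gap, ?, or IUPAC ambiguity code). Over the
# n surviving columns, with transition proportion P and transversion
# proportion Q, d = -(1/2) ln[(1 - 2P - Q) sqrt(1 - 2Q)].

PURINES <- c("A", "G")

# Per-column pair classification: 0 excluded, 1 identical, 2 transition,
# 3 transversion.
pair_codes <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  code <- integer(length(x))
  same <- ok & x == y
  diff <- ok & x != y
  ts <- diff & ((x %in% PURINES) == (y %in% PURINES))
  code[same] <- 1L
  code[ts] <- 2L
  code[diff & !ts] <- 3L
  code
}

k2p_from_counts <- function(n_same, n_ts, n_tv, labels = NULL) {
  n <- n_same + n_ts + n_tv
  who <- if (is.null(labels)) "" else sprintf(" for pair %s-%s", labels[1L],
                                              labels[2L])
  if (n == 0L)
    bd_stop("bd_undefined_distance",
            "no comparable sites after pairwise deletion%s", who)
  P <- n_ts / n
  Q <- n_tv / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    bd_stop("bd_saturation_error",
            "K2P distance inapplicable (saturated: P=%.4f, Q=%.4f)%s",
            P, Q, who)
  d <- -0.5 * log(a1 * sqrt(a2))
  attr(d, "n_sites") <- n
  d
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' @param row_i,row_j equal-length character vectors (single characters).
#' @param labels optional pair labels used in error messages.
#' @return The K2P distance (non-negative double) with attribute `n_sites`,
#'   the number of columns surviving pairwise deletion.
#' @examples
#' k2p_distance(strsplit("ACGT", "")[[1]], strsplit("ACGT", "")[[1]])  # 0
#' @export
k2p_distance <- function(row_i, row_j, labels = NULL) {
  if (length(row_i) != length(row_j))
    bd_stop("bd_contract_violation", "rows differ in length")
  code <- pair_codes(toupper(row_i), toupper(row_j))
  k2p_from_counts(sum(code == 1L), sum(code == 2L), sum(code == 3L), labels)
}

#' All pairwise K2P distances of an alignment
#'
#' @param alignment a `dna_alignment` with at least two strains.
#' @return Object of class `k2p_dist`: `labels`, symmetric matrix `d`, and
#'   matrix `n_sites` of per-pair effective site counts.
#' @export
k2p_distance_matrix <- function(alignment) {
  mat <- alignment$mat
  if (nrow(mat) < 2L)
    bd_stop("bd_contract_violation", "need at least 2 strains")
  labels <- rownames(mat)
  codes <- pair_code_matrix(mat)
  dist_from_codes(codes, labels)
}

# Pairs in row-major upper-triangle order; one integer row per pair.
pair_code_matrix <- function(mat) {
  n <- nrow(mat)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  codes <- matrix(0L, nrow(pairs), ncol(mat))
  for (k in seq_len(nrow(pairs)))
    codes[k, ] <- pair_codes(mat[pairs[k, 1L], ], mat[pairs[k, 2L], ])
  attr(codes, "pairs") <- pairs
  codes
}

dist_from_codes <- function(codes, labels, cols = NULL) {
  pairs <- attr(codes, "pairs")
  if (!is.null(cols)) codes <- codes[, cols, drop = FALSE]
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    v <- k2p_from_counts(sum(codes[k, ] == 1L), sum(codes[k, ] == 2L),
                         sum(codes[k, ] == 3L), labels = labels[c(i, j)])
    d[i, j] <- d[j, i] <- as.numeric(v)
    ns[i, j] <- ns[j, i] <- attr(v, "n_sites")
  }
  structure(list(labels = labels, d = d, n_sites = ns), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("<k2p_dist> %d strains, distances %.4g-%.4g\n",
              length(x$labels), min(x$d[upper.tri(x$d)]),
              max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Write a labeled square distance matrix to TSV
#' @param dm a `k2p_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(strain = dm$labels, dm$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
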