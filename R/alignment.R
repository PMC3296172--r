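# Alignment container, IUPAC state algebra and FASTA IO.
#
# Site coordinates are 1-based and inclusive throughout: the reference
# position of alignment column j is ref_offset + j - 1, optionally within a
# named sub-range (`regions`) when one physical alignment spans several
# reference coordinate systems (e.g. the COI tail + whole COII numbered on
# D. yakuba).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ALLOWED_CHARS <- c(names(IUPAC_SETS), "-", "?")

#' Expand an IUPAC nucleotide code to its state set
#'
#' @param code single IUPAC letter (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`).
#' @return Character vector of plain nucleotides, sorted.
#' @examples
#' iupac_to_set("R")  # A G
#' @export
iupac_to_set <- function(code) {
  stopifnot(length(code) == 1L)
  s <- IUPAC_SETS[[toupper(code)]]
  if (is.null(s))
    bd_stop("bd_format_error", "unknown IUPAC code '%s'", code)
  sort(s)
}

#' Collapse a nucleotide state set to its IUPAC code
#'
#' Inverse of [iupac_to_set()] over the 15 nonempty subsets of `{A,C,G,T}`.
#'
#' @param states character vector, nonempty subset of `A,C,G,T`.
#' @return Single IUPAC letter.
#' @export
set_to_iupac <- function(states) {
  states <- sort(unique(toupper(states)))
  if (length(states) == 0L)
    bd_stop("bd_contract_violation", "empty state set has no IUPAC code")
  if (!all(states %in% c("A", "C", "G", "T")))
    bd_stop("bd_format_error", "state set contains non-nucleotide: %s",
            paste(states, collapse = ","))
  key <- paste(states, collapse = "")
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  names(keys)[match(key, keys)]
}

#' Construct an aligned character matrix for one locus
#'
#' @param mat character matrix, rows = strains (rownames = strain ids),
#'   single uppercase characters over the IUPAC alphabet plus `-` (alignment
#'   gap) and `?` (fully missing).
#' @param locus locus name.
#' @param ref_offset 1-based reference position of the first column.
#' @param ref_name name of the reference used for site numbering.
#' @param regions optional data.frame with columns `region`, `start_col`,
#'   `end_col`, `ref_start` mapping column ranges onto named reference
#'   coordinate ranges; overrides `ref_offset` where it applies.
#' @return Object of class `dna_alignment`.
#' @export
new_alignment <- function(mat, locus, ref_offset = 1L, ref_name = locus,
                          regions = NULL) {
  stopifnot(is.matrix(mat), is.character(mat), !is.null(rownames(mat)))
  if (ncol(mat) < 1L)
    bd_stop("bd_alignment_error", "alignment '%s' has zero columns", locus)
  if (anyDuplicated(rownames(mat)))
    bd_stop("bd_format_error", "duplicate strain ids in alignment '%s'", locus)
  if (ref_offset < 1L)
    bd_stop("bd_contract_violation", "ref_offset must be >= 1")
  bad <- which(!mat %in% ALLOWED_CHARS)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(mat))
    bd_stop("bd_format_error",
            "illegal character '%s' in strain '%s' at column %d of locus '%s'",
            mat[bad[1L]], rownames(mat)[i[1L]], i[2L], locus)
  }
  structure(
    list(locus = locus, mat = mat, ref_offset = as.integer(ref_offset),
         ref_name = ref_name, regions = regions),
    class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> locus %s: %d strains x %d sites (%s, offset %d)\n",
              x$locus, nrow(x$mat), ncol(x$mat), x$ref_name, x$ref_offset))
  invisible(x)
}

#' @export
dim.dna_alignment <- function(x) dim(x$mat)

# Reference coordinate (and region label) of alignment columns.
col_to_ref <- function(alignment, cols) {
  if (is.null(alignment$regions)) {
    data.frame(region = alignment$locus,
               position = alignment$ref_offset + cols - 1L)
  } else {
    rg <- alignment$regions
    idx <- vapply(cols, function(j) {
      k <- which(j >= rg$start_col & j <= rg$end_col)
      if (length(k) != 1L)
        bd_stop("bd_contract_violation",
                "column %d of locus '%s' not covered by a region", j,
                alignment$locus)
      k
    }, 0L)
    data.frame(region = rg$region[idx],
               position = rg$ref_start[idx] + cols - rg$start_col[idx])
  }
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and `U` is normalized to `T`. All records must
#' have equal aligned length.
#'
#' @inheritParams new_alignment
#' @param path path to an aligned FASTA file.
#' @return A [new_alignment()] object.
#' @export
read_fasta_alignment <- function(path, locus, ref_offset = 1L,
                                 ref_name = locus, regions = NULL) {
  if (!file.exists(path))
    bd_stop("bd_format_error", "FASTA file not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L)
    bd_stop("bd_format_error", "no sequences in %s", path)
  txt <- toupper(as.character(seqs))
  txt <- gsub("U", "T", txt, fixed = TRUE)
  w <- nchar(txt)
  if (length(unique(w)) != 1L)
    bd_stop("bd_alignment_error",
            "ragged alignment in %s: lengths %s", path,
            paste(sort(unique(w)), collapse = ","))
  ids <- sub("\\s.*$", "", names(seqs))
  mat <- do.call(rbind, strsplit(txt, "", fixed = TRUE))
  rownames(mat) <- ids
  new_alignment(mat, locus = locus, ref_offset = ref_offset,
                ref_name = ref_name, regions = regions)
}

#' Write an alignment to FASTA
#'
#' @param alignment a `dna_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  lines <- as.vector(rbind(paste0(">", rownames(alignment$mat)),
                           apply(alignment$mat, 1L, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
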