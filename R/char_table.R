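# Per-site, per-species character-state tables: the in-memory (and TSV) form
# of published diagnostic-nucleotide tables. Substitution states are
# nucleotide sets rendered as IUPAC codes; indel characters take states
# "present:<motif>" / "absent", rendered as the motif or "-" ("/"-joined when
# a species is polymorphic).

#' Construct a character-state table
#'
#' @param locus locus name.
#' @param sites data.frame with columns `position` (1-based reference
#'   coordinate), `region`, `kind` (`substitution` or `indel`) and a
#'   list-column `states` whose elements are named lists
#'   (species -> character vector of states).
#' @param counts named integer vector: strains sequenced per species.
#' @param ref name of the reference coordinate system (display only).
#' @param verdicts optional named character vector of per-species monophyly
#'   verdicts (`monophyletic`, `non-monophyletic`, `untested`).
#' @return Object of class `char_table`.
#' @export
char_table <- function(locus, sites, counts, ref = NA_character_,
                       verdicts = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("position", "region", "kind", "states") %in% names(sites)))
  if (nrow(sites)) {
    if (any(sites$position < 1L | sites$position != floor(sites$position)))
      bd_stop("bd_format_error", "site positions must be positive integers")
    if (!all(sites$kind %in% c("substitution", "indel")))
      bd_stop("bd_format_error", "site kind must be substitution or indel")
    for (st in sites$states) {
      if (!setequal(names(st), names(counts)))
        bd_stop("bd_validation_error",
                "species in states differ from species in counts")
      if (any(lengths(st) == 0L))
        bd_stop("bd_validation_error", "empty state set in character table")
    }
    sites$states <- lapply(sites$states, function(st)
      lapply(st[names(counts)], canonical_states))
  }
  structure(list(locus = locus, ref = ref, counts = counts,
                 verdicts = verdicts, sites = sites),
            class = "char_table")
}

canonical_states <- function(x) {
  x <- unique(x)
  pres <- sort(x[startsWith(x, "present:")])
  nuc <- sort(x[x %in% c("A", "C", "G", "T")])
  other <- x[!x %in% c(pres, nuc)]
  if (length(setdiff(other, "absent")))
    bd_stop("bd_format_error", "unrecognized state '%s'",
            setdiff(other, "absent")[1L])
  c(nuc, pres, if ("absent" %in% other) "absent")
}

#' @export
print.char_table <- function(x, ...) {
  cat(sprintf("<char_table> locus %s: %d sites x %d species (N = %s)\n",
              x$locus, nrow(x$sites), length(x$counts),
              paste(x$counts, collapse = "/")))
  invisible(x)
}

render_states <- function(states, kind) {
  if (kind == "substitution") return(set_to_iupac(states))
  paste(vapply(states, function(s)
    if (s == "absent") "-" else sub("^present:", "", s), ""), collapse = "/")
}

parse_states <- function(cell, kind) {
  if (kind == "substitution") return(iupac_to_set(cell))
  parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
  if (length(parts) == 0L)
    bd_stop("bd_format_error", "empty indel state cell")
  vapply(parts, function(p) {
    if (p %in% c("-", "—", "deletion", "absent")) "absent"
    else paste0("present:", toupper(p))
  }, "", USE.NAMES = FALSE)
}

#' Read a character-state table from TSV
#'
#' The dialect has `#locus`, `#ref` and one `#species <name> <N> [verdict]`
#' metadata line per species, followed by a header row
#' `position  region  kind  <species...>`. Indel absence may be written `-`,
#' an em-dash, or `deletion`; polymorphic cells join states with `/`.
#'
#' @param path path to the TSV file.
#' @return A [char_table()].
#' @export
read_character_table <- function(path) {
  if (!file.exists(path))
    bd_stop("bd_format_error", "character table not found: %s", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  locus <- ref <- NA_character_
  counts <- integer()
  verdicts <- character()
  for (ln in meta) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "#locus") locus <- f[2L]
    if (f[1L] == "#ref") ref <- f[2L]
    if (f[1L] == "#species") {
      counts[f[2L]] <- as.integer(f[3L])
      if (length(f) >= 4L) verdicts[f[2L]] <- f[4L]
    }
  }
  if (length(body) < 1L)
    bd_stop("bd_format_error", "character table %s has no header row", path)
  hdr <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr[1:3], c("position", "region", "kind")))
    bd_stop("bd_format_error",
            "character table header must start: position, region, kind")
  species <- hdr[-(1:3)]
  if (length(counts) == 0L) counts <- stats::setNames(rep(NA_integer_,
                                                          length(species)),
                                                      species)
  rows <- lapply(body[-1L], function(ln) strsplit(ln, "\t", fixed = TRUE)[[1L]])
  pos <- vapply(rows, function(r) {
    p <- suppressWarnings(as.integer(r[1L]))
    if (is.na(p) || p < 1L)
      bd_stop("bd_format_error", "bad site position '%s'", r[1L])
    p
  }, 0L)
  sites <- data.frame(position = pos,
                      region = vapply(rows, `[`, "", 2L),
                      kind = vapply(rows, `[`, "", 3L))
  sites$states <- lapply(rows, function(r) {
    st <- lapply(seq_along(species),
                 function(k) parse_states(r[3L + k], r[3L]))
    names(st) <- species
    st
  })
  char_table(locus = locus, sites = sites, counts = counts[species],
             ref = ref, verdicts = if (length(verdicts)) verdicts else NULL)
}

#' Write a character-state table to TSV
#'
#' Lossless inverse of [read_character_table()] on canonical form.
#'
#' @param table a `char_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_character_table <- function(table, path) {
  species <- names(table$counts)
  meta <- c(sprintf("#locus\t%s", table$locus),
            if (!is.na(table$ref)) sprintf("#ref\t%s", table$ref),
            vapply(species, function(s)
              paste(c("#species", s, table$counts[[s]],
                      table$verdicts[s][!is.na(table$verdicts[s])]),
                    collapse = "\t"), ""))
  hdr <- paste(c("position", "region", "kind", species), collapse = "\t")
  rows <- vapply(seq_len(nrow(table$sites)), function(i) {
    st <- table$sites$states[[i]]
    cells <- vapply(species, function(s)
      render_states(st[[s]], table$sites$kind[i]), "")
    paste(c(table$sites$position[i], table$sites$region[i],
            table$sites$kind[i], cells), collapse = "\t")
  }, "")
  writeLines(c(meta, hdr, rows), path)
  invisible(path)
}
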