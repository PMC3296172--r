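# Newick IO, delegated to ape with a stricter up-front syntax check so that
# malformed input fails loudly rather than silently mis-parsing.

#' Parse a Newick string
#'
#' Branch lengths and internal-node (support) labels are preserved;
#' unresolved multifurcations are accepted.
#'
#' @param text a Newick string (terminated by `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L) || depth[length(depth)] != 0L)
    bd_stop("bd_parse_error", "unbalanced parentheses in Newick: %s", text)
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy))
    bd_stop("bd_parse_error", "could not parse Newick: %s", text)
  phy
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @return Newick string, semicolon-terminated.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}
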