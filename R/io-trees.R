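#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline relies on: unique tip labels and non-negative branch
#' lengths. Missing branch lengths are kept as `NA` (absent), never coerced
#' to zero.
#'
#' @param path path to a newick file (a single tree).
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    stop("newick parse failure in '", path, "' near byte ",
         newick_error_offset(txt))
  }
  validate_tree(tr)
}

## Best-effort localisation of a newick syntax error: first unbalanced
## bracket, or the end of input if brackets balance but parsing failed.
newick_error_offset <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  nchar(txt)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths")
  tr
}

#' Write a tree to a newick file
#'
#' Round-trip property: `read_newick(write_newick(t))` preserves topology
#' and branch lengths to 1e-9.
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths equal within a relative tolerance.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tol relative tolerance (default 1e-6).
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(depths) - min(depths)) <= tol * max(max(depths), .Machine$double.eps)
}
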