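#' Cophenetic (patristic) distance matrix of a tree
#'
#' d(i, j) is the sum of branch lengths on the path between tips i and j.
#'
#' @param tree a `phylo` with branch lengths on every edge.
#' @return a labelled symmetric matrix with zero diagonal, tips in
#'   `tree$tip.label` order.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has absent branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  diag(d) <- 0
  validate_distance_matrix(d)
  d
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree; degree-2 nodes are collapsed with branch
#' lengths summed, so cophenetic distances among retained taxa are
#' preserved.
#'
#' @param tree a `phylo`.
#' @param taxa character vector of tip labels to keep (at least 2).
#' @return a `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(unique(taxa)) < 2) stop("need at least 2 taxa to prune to")
  ape::keep.tip(tree, taxa)
}

#' Read a node-age map from CSV
#'
#' Two columns: node label, age (Myr before present).
#'
#' @param path CSV file path.
#' @return named numeric vector of ages.
#' @export
read_node_ages <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ages <- as.numeric(df[[2]])
  names(ages) <- as.character(df[[1]])
  if (any(!is.finite(ages)) || any(ages < 0)) stop("ages must be finite and >= 0")
  ages
}

#' Date undated nodes by even interpolation (BLADJ-style)
#'
#' Given fixed ages for some internal nodes (matched by `tree$node.label`;
#' the root must be dated; tips are implicitly age 0), every undated node
#' receives an age by evenly spacing the nodes lying between consecutive
#' dated anchors: on a path from a dated ancestor to its nearest dated
#' descendant (or tip) holding k undated nodes, the age interval is split
#' into k + 1 equal steps. When an undated node lies on paths to several
#' dated descendants, the path anchored on the oldest dated descendant wins
#' (ties: the fewest intervening edges, then node order) — mirroring the
#' oldest-first processing order of the original algorithm, which also
#' guarantees parent ages never fall below child ages. Branch lengths are
#' recomputed as parent age minus child age, so the output is ultrametric
#' and dated nodes keep their ages exactly. Fully dated trees pass through
#' unchanged (idempotence).
#'
#' @param tree a rooted `phylo` with `node.label`s identifying internal
#'   nodes (labels need not be unique for undated nodes, but dated labels
#'   must be).
#' @param known named numeric vector: node label -> age (Myr).
#' @return a dated ultrametric `phylo`; node ages in attribute `node_ages`
#'   (indexed by internal node number).
#' @export
bladj_date <- function(tree, known) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  if (is.null(tree$node.label)) stop("tree has no node labels to date by")
  root <- ntip + 1L
  lab <- tree$node.label
  ages <- rep(NA_real_, ntip + nnode)     # full node-age vector, tips age 0
  ages[seq_len(ntip)] <- 0
  for (nm in names(known)) {
    hit <- which(lab == nm)
    if (length(hit) > 1) stop("dated node label not unique: ", nm)
    if (length(hit) == 1) ages[ntip + hit] <- known[[nm]]
  }
  if (is.na(ages[root])) stop("root must be dated")

  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])

  ## check consistency of the supplied ages
  for (v in which(!is.na(ages))) {
    p <- parent[v]
    while (p != 0L) {
      if (!is.na(ages[p]) && ages[p] < ages[v] - 1e-9)
        stop("inconsistent known ages: ancestor younger than descendant")
      p <- parent[p]
    }
  }

  dated <- !is.na(ages)
  ## anchor of every node = its oldest dated descendant (ties: fewest
  ## intervening edges, then node id), found by a post-order sweep
  ord <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2])
  post <- c(rev(ord), root)                     # children before parents
  nd_age <- rep(NA_real_, ntip + nnode)
  nd_dist <- rep(NA_integer_, ntip + nnode)
  for (v in post) {
    if (dated[v]) { nd_age[v] <- ages[v]; nd_dist[v] <- 0L; next }
    best_d <- NA_integer_; best_a <- NA_real_
    for (ch in children[[as.character(v)]]) {
      d <- nd_dist[ch] + 1L; a <- nd_age[ch]
      if (is.na(best_d) || a > best_a || (a == best_a && d < best_d)) {
        best_d <- d; best_a <- a
      }
    }
    nd_dist[v] <- best_d; nd_age[v] <- best_a
  }

  ## pre-order: every undated node interpolates between its (already
  ## resolved) parent age and its nearest dated descendant.
  pre <- c(root, ord)
  for (v in pre) {
    if (dated[v]) next
    pa <- ages[parent[v]]
    k <- nd_dist[v]                     # edges from v down to its anchor
    ages[v] <- nd_age[v] + (pa - nd_age[v]) * k / (k + 1)
  }

  bad <- tree$edge[ages[tree$edge[, 1]] < ages[tree$edge[, 2]] - 1e-9, , drop = FALSE]
  if (nrow(bad)) stop("age interpolation produced a parent younger than its child")

  out <- tree
  out$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  attr(out, "node_ages") <- ages[(ntip + 1L):(ntip + nnode)]
  out
}
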