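#' Generalized Gower distance over mixed traits
#'
#' d(i,j) = sqrt( sum_t w_t * delta_t(i,j) / sum_t w_t ), the sums running
#' over traits non-missing in both species (pairwise deletion). Per-trait
#' dissimilarities are range-scaled so each lies in \[0, 1\]:
#' continuous traits use the squared difference divided by the squared
#' range over species with a value; unordered categoricals the 0/1
#' mismatch indicator; ordered categoricals the squared rank difference
#' divided by the squared rank range. The square-root aggregation keeps the
#' distance Euclidean-embeddable, which keeps UPGMA well behaved.
#'
#' @param traits a `trait_table` (standardize continuous traits first with
#'   [standardize_traits()]; the range scaling makes the distance invariant
#'   to that, but both steps are part of the documented procedure).
#' @param weights optional named (or schema-ordered) non-negative trait
#'   weights; default equal.
#' @return labelled distance matrix (species x species).
#' @export
gower_distance <- function(traits, weights = NULL) {
  sch <- traits$schema
  vals <- traits$values
  n <- nrow(vals)
  p <- nrow(sch)
  if (p < 1) stop("need at least one trait")
  if (is.null(weights)) weights <- rep(1, p)
  if (!is.null(names(weights))) weights <- weights[sch$trait]
  if (length(weights) != p || any(is.na(weights)) || any(weights < 0) ||
      sum(weights) == 0)
    stop("weights must be non-negative, one per trait, not all zero")

  num <- matrix(0, n, n)   # sum of w_t * delta_t over shared traits
  den <- matrix(0, n, n)   # sum of w_t over shared traits
  for (t in seq_len(p)) {
    w <- weights[t]
    if (w == 0) next
    if (sch$kind[t] == "continuous") {
      x <- vals[[t]]
    } else if (isTRUE(sch$ordered[t])) {
      x <- as.numeric(match(vals[[t]], trait_states(sch, sch$trait[t])))
    } else {
      x <- NULL
    }
    if (!is.null(x)) {                 # quantitative or ranked
      ok <- !is.na(x)
      rng <- if (sum(ok) >= 2) diff(range(x[ok])) else 0
      dif <- outer(x, x, "-")
      delta <- if (rng > 0) (dif / rng)^2 else dif * 0
    } else {                           # unordered categorical
      s <- vals[[t]]
      delta <- outer(s, s, "!=") * 1
      ok <- !is.na(s)
    }
    shared <- outer(ok, ok, "&")
    delta[!shared] <- 0
    num <- num + w * delta
    den <- den + w * shared
  }
  if (any(den == 0 & upper.tri(den)))
    stop("species pair with no shared non-missing trait")
  d <- sqrt(num / den)
  diag(d) <- 0
  dimnames(d) <- list(rownames(vals), rownames(vals))
  validate_distance_matrix(d)
  d
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Repeatedly merges the pair of clusters with the smallest average
#' inter-cluster distance; the merged cluster's distance to the rest is the
#' size-weighted mean. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest member).
#'
#' @param dist labelled distance matrix.
#' @return an object of class `hclust` (method `"average"`), usable with
#'   the standard dendrogram tooling and with [dendrogram_to_tree()].
#' @export
upgma <- function(dist) {
  validate_distance_matrix(dist)
  labels <- rownames(dist)
  n <- length(labels)
  if (n < 2) stop("need at least 2 labels")
  d <- dist
  size <- rep(1L, n)
  id <- -seq_len(n)                     # hclust convention: negatives = leaves
  clab <- labels                        # cluster label = smallest member label
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mn <- min(sub)
    hits <- which(sub == mn, arr.ind = TRUE)
    if (nrow(hits) > 1) {               # lexicographic tie-break on label pairs
      keys <- apply(hits, 1, function(h) {
        pr <- sort(c(clab[idx[h[1]]], clab[idx[h[2]]]))
        paste(pr, collapse = "\r")
      })
      hits <- hits[order(keys)[1], , drop = FALSE]
    }
    i <- idx[hits[1, 1]]; j <- idx[hits[1, 2]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- mn
    new_d <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- new_d; d[, i] <- new_d; d[i, i] <- 0
    size[i] <- size[i] + size[j]
    clab[i] <- min(clab[i], clab[j])
    id[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge), labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "user"),
            class = "hclust")
}

## leaf ordering with no crossings, derived from the merge matrix
hclust_order <- function(merge) {
  walk <- function(row) {
    unlist(lapply(merge[row, ], function(v)
      if (v < 0) -v else walk(v)))
  }
  walk(nrow(merge))
}

#' Convert a dendrogram to an ultrametric phylogenetic tree
#'
#' Node ages are half the merge heights, so the cophenetic distance between
#' two tips in the resulting tree equals the height at which they merge.
#' This lets phylogenetic and phenotypic community metrics run on the same
#' machinery.
#'
#' @param dend an `hclust` object (e.g. from [upgma()]).
#' @return an ultrametric `phylo`.
#' @export
dendrogram_to_tree <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  tr <- ape::as.phylo(dend)             # uses the height/2 convention
  validate_tree(tr)
}
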