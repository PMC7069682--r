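## Phylogenetic-signal tests: independent contrasts (continuous traits) and
## Fitch/Hartigan minimum state changes (categorical traits), each compared
## to a null of randomly permuting the trait values across the tips.

## Resolve polytomies to zero-length branches, then replace zero/absent
## lengths by eps = 1e-6 * tree depth so contrast variances stay positive.
prepare_pic_tree <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  depth <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-6 * max(depth, .Machine$double.eps)
  tree$edge.length[is.na(tree$edge.length) | tree$edge.length <= 0] <- eps
  tree
}

## Felsenstein's pruning pass expressed as a linear map: contrasts = C %*% x
## for any tip-value vector x (the variance bookkeeping does not depend on
## the values, so C is computed once per tree and permutation nulls become
## one matrix product). Rows are ordered by internal node number.
pic_linear_map <- function(tree) {
  tree <- prepare_pic_tree(tree)
  ntip <- ape::Ntip(tree)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  nnode <- tree$Nnode
  coefs <- matrix(0, ntip + nnode, ntip)       # node value as combo of tips
  coefs[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  v <- numeric(ntip + nnode)                   # accumulated variance per node
  v[edge[, 2]] <- elen
  C <- matrix(0, nnode, ntip)
  i <- 1L
  while (i <= nrow(edge)) {                    # postorder blocks per node
    node <- edge[i, 1]
    j <- i
    while (j <= nrow(edge) && edge[j, 1] == node) j <- j + 1L
    ch <- edge[i:(j - 1L), 2]
    stopifnot(length(ch) == 2)                 # guaranteed by prepare_pic_tree
    v1 <- v[ch[1]]; v2 <- v[ch[2]]
    C[node - ntip, ] <- (coefs[ch[1], ] - coefs[ch[2], ]) / sqrt(v1 + v2)
    coefs[node, ] <- (coefs[ch[1], ] / v1 + coefs[ch[2], ] / v2) /
      (1 / v1 + 1 / v2)
    v[node] <- v[node] + v1 * v2 / (v1 + v2)
    i <- j
  }
  colnames(C) <- tree$tip.label
  C
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node with child values
#' and variances (x1, v1), (x2, v2), the standardized contrast is
#' (x1 - x2) / sqrt(v1 + v2); the node value is the variance-weighted mean
#' and its branch is extended by v1 v2 / (v1 + v2). Polytomies are resolved
#' arbitrarily to zero-length branches first (then padded by a tiny epsilon).
#'
#' @param tree a `phylo` with branch lengths.
#' @param trait named numeric vector, one value per tip.
#' @return numeric vector of `n_tips - 1` contrasts.
#' @export
pic_contrasts <- function(tree, trait) {
  x <- align_trait(tree, trait)
  C <- pic_linear_map(tree)
  drop(C %*% x)
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(tree)) stop("trait length != number of tips")
    names(trait) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stop("missing tip value(s): ", paste(miss, collapse = ", "))
  x <- trait[tree$tip.label]
  if (anyNA(x)) stop("missing tip value(s)")
  x
}

#' Phylogenetic-signal test for a continuous trait
#'
#' Compares the observed contrast statistic to a null obtained by randomly
#' permuting the trait values across the tips of the tree. Conserved traits
#' yield small contrasts, so signal shows as a low observed value: the
#' p-value is the lower-tail rank (count(null <= obs) + 1) / (n_iter + 1).
#'
#' @param tree a `phylo` with branch lengths.
#' @param trait named numeric vector of tip values.
#' @param n_iter number of randomizations (default 999).
#' @param seed optional integer seed.
#' @param stat `"variance"` (variance of contrasts, the default) or
#'   `"mean_abs"` (mean absolute contrast).
#' @param trait_name label carried into the result.
#' @return a `signal_result` list: `trait`, `kind`, `statistic`, `observed`,
#'   `null_mean`, `p`, `n_iter`, `seed`.
#' @export
continuous_signal_test <- function(tree, trait, n_iter = 999, seed = NULL,
                                   stat = c("variance", "mean_abs"),
                                   trait_name = deparse(substitute(trait))) {
  stat <- match.arg(stat)
  stopifnot(n_iter >= 1)
  x <- align_trait(tree, trait)
  C <- pic_linear_map(tree)
  stat_fun <- if (stat == "variance") {
    function(m) apply(m, 2, var)
  } else {
    function(m) colMeans(abs(m))
  }
  observed <- stat_fun(C %*% matrix(x, ncol = 1))
  null <- with_seed(seed, {
    perm <- vapply(seq_len(n_iter), function(i) x[sample.int(length(x))],
                   numeric(length(x)))
    stat_fun(C %*% perm)
  })
  p <- (sum(null <= observed) + 1) / (n_iter + 1)
  structure(list(trait = trait_name, kind = "continuous",
                 statistic = paste0("PIC-", stat), observed = observed,
                 null_mean = mean(null), p = p, n_iter = n_iter, seed = seed),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("signal_result [%s] %s: obs %.4g, null mean %.4g, p = %.4g (%d perms)\n",
              x$kind, x$trait, x$observed, x$null_mean, x$p, x$n_iter))
  invisible(x)
}

## Hartigan's generalization of the Fitch pass, vectorized over columns of
## a tip-state matrix: at each internal node, keep the states contained in
## a maximal number of child sets and add (n_children - max count) changes.
## Exact minimum-change count for rooted trees with polytomies.
fitch_changes_multi <- function(tree, state_mat, k) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nperm <- ncol(state_mat)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- vector("list", ntip + nnode)      # per node: nperm x k logical
  for (tp in seq_len(ntip)) {
    m <- matrix(FALSE, nperm, k)
    m[cbind(seq_len(nperm), state_mat[tp, ])] <- TRUE
    sets[[tp]] <- m
  }
  changes <- numeric(nperm)
  i <- 1L
  while (i <= nrow(edge)) {
    node <- edge[i, 1]
    j <- i
    while (j <= nrow(edge) && edge[j, 1] == node) j <- j + 1L
    ch <- edge[i:(j - 1L), 2]
    count <- Reduce(`+`, lapply(ch, function(c) sets[[c]]))
    mx <- do.call(pmax, lapply(seq_len(k), function(s) count[, s]))
    sets[[node]] <- count == mx
    changes <- changes + (length(ch) - mx)
    sets[ch] <- list(NULL)
    i <- j
  }
  changes
}

#' Minimum number of character state changes (unordered parsimony)
#'
#' Fitch down-pass count, generalized to polytomies by Hartigan's
#' majority-intersection rule.
#'
#' @param tree a rooted `phylo`.
#' @param trait named character (or factor) vector of tip states.
#' @return integer minimum change count.
#' @export
fitch_changes <- function(tree, trait) {
  s <- align_states(tree, trait)
  states <- sort(unique(s))
  as.integer(fitch_changes_multi(tree, matrix(match(s, states), ncol = 1),
                                 length(states)))
}

align_states <- function(tree, trait) {
  if (is.factor(trait)) {
    nm <- names(trait); trait <- as.character(trait); names(trait) <- nm
  }
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(tree)) stop("trait length != number of tips")
    names(trait) <- tree$tip.label
  }
  s <- trait[tree$tip.label]
  if (anyNA(s)) stop("missing tip state(s)")
  s
}

#' Phylogenetic-signal test for a categorical trait
#'
#' Compares the observed minimum change count to a null in which the tip
#' states are randomly permuted across the tips; related species sharing
#' states yield fewer changes than expected at random, so the p-value is
#' the lower-tail rank (count(null <= obs) + 1) / (n_iter + 1).
#'
#' @inheritParams continuous_signal_test
#' @param trait named character vector of tip states.
#' @return a `signal_result`.
#' @export
categorical_signal_test <- function(tree, trait, n_iter = 999, seed = NULL,
                                    trait_name = deparse(substitute(trait))) {
  stopifnot(n_iter >= 1)
  s <- align_states(tree, trait)
  states <- sort(unique(s))
  k <- length(states)
  si <- match(s, states)
  observed <- fitch_changes_multi(tree, matrix(si, ncol = 1), k)
  null <- with_seed(seed, {
    perm <- vapply(seq_len(n_iter), function(i) si[sample.int(length(si))],
                   integer(length(si)))
    fitch_changes_multi(tree, perm, k)
  })
  p <- (sum(null <= observed) + 1) / (n_iter + 1)
  structure(list(trait = trait_name, kind = "categorical",
                 statistic = "parsimony-changes", observed = observed,
                 null_mean = mean(null), p = p, n_iter = n_iter, seed = seed),
            class = "signal_result")
}

#' Phylogenetic-signal table for every trait in a trait table
#'
#' Runs [continuous_signal_test()] or [categorical_signal_test()] per trait
#' against the supplied phylogeny and collects a tidy table (trait, role,
#' kind, observed, null mean, p).
#'
#' @param tree a `phylo` whose tips cover the trait table species.
#' @param traits a `trait_table`.
#' @param n_iter randomizations per trait (default 999).
#' @param seed optional master seed (per-trait substreams derived from it).
#' @param stat statistic for continuous traits (see
#'   [continuous_signal_test()]).
#' @return data.frame, one row per trait.
#' @export
signal_table <- function(tree, traits, n_iter = 999, seed = NULL,
                         stat = "variance") {
  sp <- trait_species(traits)
  miss <- setdiff(sp, tree$tip.label)
  if (length(miss)) stop("species absent from tree: ", paste(miss, collapse = ", "))
  tr <- if (length(setdiff(tree$tip.label, sp))) prune_to_taxa(tree, sp) else tree
  rows <- lapply(seq_len(nrow(traits$schema)), function(i) {
    nm <- traits$schema$trait[i]
    v <- traits$values[[nm]]
    names(v) <- sp
    keep <- !is.na(v)
    sub <- if (all(keep)) tr else prune_to_taxa(tr, sp[keep])
    res <- if (traits$schema$kind[i] == "continuous") {
      continuous_signal_test(sub, v[keep], n_iter = n_iter,
                             seed = derive_seed(seed, nm), stat = stat,
                             trait_name = nm)
    } else {
      categorical_signal_test(sub, v[keep], n_iter = n_iter,
                              seed = derive_seed(seed, nm), trait_name = nm)
    }
    data.frame(trait = nm, role = traits$schema$role[i], kind = res$kind,
               statistic = res$statistic, observed = res$observed,
               null_mean = res$null_mean, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
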