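## Independent brute-force oracles and small fixture builders. Oracles are
## deliberately naive (double loops, exhaustive enumeration) so they share
## no code path with the implementation they check.

naive_mpd <- function(species, d) {
  s <- 0; n <- 0
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i < j) {
      s <- s + d[species[i], species[j]]
      n <- n + 1
    }
  }
  s / n
}

naive_between_mpd <- function(sp_i, sp_j, d) {
  s <- 0; n <- 0
  for (a in sp_i) for (b in sp_j) {
    s <- s + d[a, b]
    n <- n + 1
  }
  s / n
}

## O(n^3) UPGMA keeping explicit member lists; returns the merge trace as a
## list of (sorted member sets of the two clusters, height).
naive_upgma_trace <- function(d) {
  clusters <- lapply(rownames(d), identity)
  trace <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    trace[[length(trace) + 1]] <- list(
      a = sort(clusters[[best[1]]]), b = sort(clusters[[best[2]]]),
      height = best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  trace
}

## Extract the same trace shape from an hclust object.
hclust_trace <- function(h) {
  members <- vector("list", nrow(h$merge))
  lapply(seq_len(nrow(h$merge)), function(s) {
    get_m <- function(v) if (v < 0) h$labels[-v] else members[[v]]
    a <- get_m(h$merge[s, 1]); b <- get_m(h$merge[s, 2])
    members[[s]] <<- c(a, b)
    list(a = sort(a), b = sort(b), height = h$height[s])
  })
}

## Exhaustive minimum state changes: enumerate every assignment of states
## to internal nodes and count mismatched edges. Feasible for <= 8 tips.
brute_fitch <- function(tree, states) {
  k_states <- sort(unique(states))
  k <- length(k_states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tip_idx <- match(states[tree$tip.label], k_states)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(tip_idx, grid[g, ])
    cost <- sum(assign_all[tree$edge[, 1]] != assign_all[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

## Random labelled distance matrix (metric not required by UPGMA).
random_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 1, 10), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  m
}

## Small mixed-trait fixture mirroring the field's 11-trait design:
## 7 alpha (5 continuous + ordered dispersule size + binary phenology),
## 4 beta (2 continuous + 2 unordered categoricals).
paper_like_traits <- function(n = 12, seed = 1) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n))
  vals <- data.frame(
    max_height = rlnorm(n, 2, 0.5),
    mean_biomass = rlnorm(n, 0, 1),
    sla = rnorm(n, 15, 4),
    leaf_n = rnorm(n, 20, 5),
    conductivity = rlnorm(n, 5, 1),
    dispersule_size = sample(c("small", "medium", "large", "very_large"),
                             n, replace = TRUE),
    phenology = sample(c("deciduous", "evergreen"), n, replace = TRUE),
    leaf_size = rlnorm(n, 8, 1),
    wood_density = rnorm(n, 0.6, 0.15),
    dispersal_mode = sample(c("anemochory", "autochory", "barochory",
                              "zoochory"), n, replace = TRUE),
    leaf_type = sample(c("simple", "compound", "bicompound"), n,
                       replace = TRUE),
    row.names = sp, stringsAsFactors = FALSE)
  schema <- data.frame(
    trait = names(vals),
    kind = c(rep("continuous", 5), "categorical", "categorical",
             "continuous", "continuous", "categorical", "categorical"),
    role = c(rep("alpha", 7), rep("beta", 4)),
    states = c(rep(NA, 5), "small|medium|large|very_large",
               "deciduous|evergreen", NA, NA,
               "anemochory|autochory|barochory|zoochory",
               "simple|compound|bicompound"),
    ordered = c(rep(FALSE, 5), TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE)
  trait_table(vals, schema)
}
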