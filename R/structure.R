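#' Mean pairwise distance among a species set
#'
#' Unweighted mean of d(i, j) over all unordered pairs within the set.
#' With a phylogenetic cophenetic matrix this is MPD; with the cophenetic
#' matrix of a functional tree it is the mean pairwise trait distance PW.
#'
#' @param species character vector of labels (>= 2, all in `dist`).
#' @param dist labelled distance matrix.
#' @return numeric scalar.
#' @export
mpd <- function(species, dist) {
  species <- unique(species)
  miss <- setdiff(species, rownames(dist))
  if (length(miss)) stop("species absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  r <- length(species)
  if (r < 2) stop("need at least 2 species for a pairwise mean")
  sub <- dist[species, species]
  sum(sub) / (r * (r - 1))
}

#' @rdname mpd
#' @export
pw <- mpd

## Metric over rows of an index matrix (nulls are drawn as tip indices into
## the pool once and evaluated against any number of distance matrices).
mpd_by_index <- function(idx_mat, dist) {
  vapply(seq_len(nrow(idx_mat)), function(i) {
    id <- idx_mat[i, ]
    r <- length(id)
    sum(dist[id, id]) / (r * (r - 1))
  }, numeric(1))
}

#' Regional-pool null distribution for MPD/PW
#'
#' Each iteration draws `richness` species uniformly without replacement
#' from the regional pool and recomputes the metric (the phylogeny.pool
#' randomization: equiprobable species, richness held at the observed
#' value).
#'
#' @param richness observed species richness (>= 2, <= pool size).
#' @param pool character vector: the regional species pool.
#' @param dist labelled distance matrix covering the pool.
#' @param n_iter number of random draws (default 999).
#' @param seed optional integer seed.
#' @return object of class `null_distribution`: `values`, `algorithm`,
#'   `metric`, `n_iter`, `seed`, `pool_size`; degenerate nulls (zero SD)
#'   carry `degenerate = TRUE`.
#' @export
phylogeny_pool_null <- function(richness, pool, dist, n_iter = 999,
                                seed = NULL) {
  pool <- unique(pool)
  if (richness > length(pool)) stop("richness exceeds pool size")
  if (richness < 2) stop("richness must be >= 2")
  miss <- setdiff(pool, rownames(dist))
  if (length(miss)) stop("pool species absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  idx <- with_seed(seed, pool_draws(length(pool), richness, n_iter))
  d <- dist[pool, pool]
  vals <- mpd_by_index(idx, d)
  structure(list(values = vals, algorithm = "phylogeny.pool", metric = "mpd",
                 n_iter = n_iter, seed = seed, pool_size = length(pool),
                 degenerate = sd(vals) == 0),
            class = "null_distribution")
}

pool_draws <- function(pool_size, richness, n_iter) {
  t(vapply(seq_len(n_iter),
           function(i) sample.int(pool_size, richness),
           integer(richness)))
}

#' Classify a community pattern from its permutation p-value
#'
#' p <= `lower` is clustered, p >= `upper` overdispersed, anything between
#' random.
#'
#' @param p permutation p-value (lower tail).
#' @param lower,upper thresholds (defaults 0.025 / 0.975).
#' @return `"clustered"`, `"random"` or `"overdispersed"`.
#' @export
classify_pattern <- function(p, lower = 0.025, upper = 0.975) {
  stopifnot(lower > 0, lower < 0.5, upper > 0.5, upper < 1)
  ifelse(p <= lower, "clustered", ifelse(p >= upper, "overdispersed", "random"))
}

#' Standardized effect size of an observed metric against its null
#'
#' SES = (observed - null mean) / null SD. The permutation p-value uses the
#' mid-p rank rule, p = (count(null < obs) + 0.5 count(null = obs) + 1) /
#' (n_iter + 1). The null's shape is checked (Shapiro-Wilk and skewness);
#' when normality fails (p < 0.05) or |skewness| > 0.5, a rank-based
#' corrected SES, probit of the mid-p, is reported alongside the raw value
#' with `corrected = TRUE`.
#'
#' @param observed observed metric value.
#' @param null a `null_distribution` (or bare numeric vector).
#' @param lower,upper classification thresholds (see [classify_pattern()]).
#' @return list of class `ses_result`: `observed`, `null_mean`, `null_sd`,
#'   `ses`, `ses_corrected`, `corrected`, `normality_p`, `skewness`, `p`,
#'   `pattern`.
#' @export
ses <- function(observed, null, lower = 0.025, upper = 0.975) {
  vals <- if (inherits(null, "null_distribution")) null$values else null
  m <- mean(vals); s <- sd(vals)
  if (s == 0) stop("degenerate null distribution (SD = 0)")
  n <- length(vals)
  p <- (sum(vals < observed) + 0.5 * sum(vals == observed) + 1) / (n + 1)
  sw <- if (n >= 3 && n <= 5000) shapiro.test(vals)$p.value else NA_real_
  sk <- skewness(vals)
  corrected <- (!is.na(sw) && sw < 0.05) || abs(sk) > 0.5
  structure(list(observed = observed, null_mean = m, null_sd = s,
                 ses = (observed - m) / s,
                 ses_corrected = if (corrected) qnorm(p) else NA_real_,
                 corrected = corrected, normality_p = sw, skewness = sk,
                 p = p, pattern = classify_pattern(p, lower, upper)),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("ses_result: obs %.4g, null %.4g +/- %.4g, SES %.3f%s, p = %.4g (%s)\n",
              x$observed, x$null_mean, x$null_sd, x$ses,
              if (x$corrected) sprintf(" (corrected %.3f)", x$ses_corrected) else "",
              x$p, x$pattern))
  invisible(x)
}

ses_row <- function(site, metric, s) {
  data.frame(site = site, metric = metric, observed = s$observed,
             null_mean = s$null_mean, null_sd = s$null_sd, ses = s$ses,
             ses_corrected = s$ses_corrected, corrected = s$corrected,
             normality_p = s$normality_p, skewness = s$skewness, p = s$p,
             pattern = s$pattern, stringsAsFactors = FALSE)
}

#' Build the cophenetic distance matrices used by the structure analysis
#'
#' Phylogenetic distances from the supplied tree, and phenotypic distances
#' from functional trees (standardize -> generalized Gower -> UPGMA ->
#' ultrametric tree) built on all traits, alpha traits only and beta traits
#' only.
#'
#' @param tree regional phylogeny (`phylo`).
#' @param traits a `trait_table` covering the pool species.
#' @param gower_weights optional per-trait weights (see [gower_distance()]).
#' @return named list of distance matrices: `mpd`, `pw`, `pw_alpha`,
#'   `pw_beta`.
#' @export
structure_distances <- function(tree, traits, gower_weights = NULL) {
  std <- standardize_traits(traits)
  fun_dist <- function(role) {
    tt <- partition_traits(std, role)
    w <- if (is.null(gower_weights)) NULL else gower_weights[tt$schema$trait]
    cophenetic_distances(dendrogram_to_tree(upgma(gower_distance(tt, w))))
  }
  list(mpd = cophenetic_distances(tree),
       pw = fun_dist("all"), pw_alpha = fun_dist("alpha"),
       pw_beta = fun_dist("beta"))
}

#' Phylogenetic and phenotypic community structure along the gradient
#'
#' For every site computes the SES of MPD (phylogeny) and of PW, PW-alpha
#' and PW-beta (functional trees on all / competition / tolerance traits)
#' under the phylogeny.pool null: random draws from the regional pool (all
#' species in the community matrix) at the observed richness. The same
#' seeded draws are reused across the four metrics of a site (common
#' random numbers), stabilizing cross-metric comparisons.
#'
#' @param comm a `community_matrix`; its species are the regional pool.
#' @param tree regional phylogeny covering the pool.
#' @param traits a `trait_table` covering the pool.
#' @param n_iter null-model iterations per site (default 999).
#' @param seed optional master seed (per-site substreams derived from it).
#' @param lower,upper classification thresholds.
#' @param gower_weights optional Gower weights.
#' @param null_out optional directory: dump every null distribution as CSV
#'   (`null_<site>.csv`, one column per metric) for shape diagnostics.
#' @return data.frame, one row per site x metric, with observed value, null
#'   mean/SD, raw and corrected SES, shape diagnostics, mid-p and pattern.
#' @export
run_structure_analysis <- function(comm, tree, traits, n_iter = 999,
                                   seed = NULL, lower = 0.025, upper = 0.975,
                                   gower_weights = NULL, null_out = NULL) {
  pool <- colnames(comm$incidence)
  miss <- setdiff(pool, tree$tip.label)
  if (length(miss)) stop("pool species absent from tree: ",
                         paste(miss, collapse = ", "))
  dists <- structure_distances(
    if (length(setdiff(tree$tip.label, pool))) prune_to_taxa(tree, pool) else tree,
    traits, gower_weights)
  dists <- lapply(dists, function(d) d[pool, pool])
  if (!is.null(null_out))
    dir.create(null_out, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (site in rownames(comm$incidence)) {
    sp <- site_species(comm, site)
    r <- length(sp)
    idx <- with_seed(derive_seed(seed, paste0("site:", site)),
                     pool_draws(length(pool), r, n_iter))
    null_dump <- list()
    for (metric in names(dists)) {
      d <- dists[[metric]]
      obs <- mpd(sp, d)
      nullv <- structure(list(values = mpd_by_index(idx, d),
                              algorithm = "phylogeny.pool", metric = metric,
                              n_iter = n_iter, seed = seed,
                              pool_size = length(pool)),
                         class = "null_distribution")
      rows[[length(rows) + 1L]] <-
        ses_row(site, metric, ses(obs, nullv, lower, upper))
      null_dump[[metric]] <- nullv$values
    }
    if (!is.null(null_out))
      write.csv(as.data.frame(null_dump),
                file.path(null_out, paste0("null_", site, ".csv")),
                row.names = FALSE)
  }
  do.call(rbind, rows)
}

#' Mean pairwise distance between two communities
#'
#' Mean of d(a, b) over all inter-community pairs a in site i, b in site j
#' (shared species contribute zero-distance pairs).
#'
#' @param species_i,species_j character vectors of species present at the
#'   two sites.
#' @param dist labelled distance matrix.
#' @return numeric scalar.
#' @export
between_community_mpd <- function(species_i, species_j, dist) {
  if (!length(species_i) || !length(species_j)) stop("empty site")
  miss <- setdiff(c(species_i, species_j), rownames(dist))
  if (length(miss)) stop("species absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  mean(dist[species_i, species_j, drop = FALSE])
}

#' Phylobetadiversity and distance decay
#'
#' For every pair of sites computes the SES of the between-community MPD
#' under the phylogeny.pool null (both memberships redrawn from the pool at
#' the observed richnesses), plus a turnover component — the Rao-style
#' additive partition, betaMPD minus the mean of the two within-site
#' quadratic entropies (mean distance over all ordered within-site pairs,
#' self-pairs included), which is exactly zero for identical compositions. The decay test is a Mantel permutation
#' correlation between turnover and great-circle distance (haversine, km).
#'
#' @param comm a `community_matrix` with `latitude`/`longitude` metadata.
#' @param tree regional phylogeny covering the pool.
#' @param n_iter null iterations per pair and Mantel permutations.
#' @param seed optional master seed.
#' @param decay if `FALSE`, skip the Mantel test (no coordinates needed).
#' @return list of class `phylobeta_result`: `pairs` (data.frame: site_i,
#'   site_j, beta_mpd, null mean/SD, ses, p, pattern, turnover, distance_km),
#'   `mantel_r`, `mantel_p` (NA with `decay_defined = FALSE` when turnover
#'   is constant).
#' @export
phylobeta_analysis <- function(comm, tree, n_iter = 999, seed = NULL,
                               decay = TRUE) {
  pool <- colnames(comm$incidence)
  d <- cophenetic_distances(
    if (length(setdiff(tree$tip.label, pool))) prune_to_taxa(tree, pool) else tree)
  d <- d[pool, pool]
  sites <- rownames(comm$incidence)
  ns <- length(sites)
  if (decay) {
    md <- comm$metadata
    if (is.null(md) || !all(c("latitude", "longitude") %in% names(md)))
      stop("site coordinates (latitude, longitude) required for decay test")
  }
  within <- vapply(sites, function(s) {   # Rao quadratic entropy per site
    sp <- site_species(comm, s)
    mean(d[sp, sp])
  }, numeric(1))
  pairs <- list()
  turn <- matrix(0, ns, ns, dimnames = list(sites, sites))
  geo <- matrix(0, ns, ns, dimnames = list(sites, sites))
  for (i in seq_len(ns - 1)) for (j in seq((i + 1), ns)) {
    sp_i <- site_species(comm, sites[i]); sp_j <- site_species(comm, sites[j])
    obs <- between_community_mpd(sp_i, sp_j, d)
    nullv <- with_seed(derive_seed(seed, paste("pair", i, j)), {
      vapply(seq_len(n_iter), function(it) {
        a <- sample.int(length(pool), length(sp_i))
        b <- sample.int(length(pool), length(sp_j))
        mean(d[a, b])
      }, numeric(1))
    })
    s <- if (sd(nullv) == 0) {            # pool = community at both sites
      list(null_mean = mean(nullv), null_sd = 0, ses = NA_real_,
           p = NA_real_, pattern = "degenerate")
    } else ses(obs, nullv)
    tv <- obs - (within[i] + within[j]) / 2
    turn[i, j] <- turn[j, i] <- tv
    gk <- if (decay)
      geosphere::distHaversine(
        c(comm$metadata$longitude[i], comm$metadata$latitude[i]),
        c(comm$metadata$longitude[j], comm$metadata$latitude[j])) / 1000
    else NA_real_
    geo[i, j] <- geo[j, i] <- gk
    pairs[[length(pairs) + 1L]] <- data.frame(
      site_i = sites[i], site_j = sites[j], beta_mpd = obs,
      null_mean = s$null_mean, null_sd = s$null_sd, ses = s$ses, p = s$p,
      pattern = s$pattern, turnover = tv, distance_km = gk,
      stringsAsFactors = FALSE)
  }
  out <- list(pairs = do.call(rbind, pairs), mantel_r = NA_real_,
              mantel_p = NA_real_, decay_defined = FALSE)
  if (decay) {
    if (sd(turn[lower.tri(turn)]) == 0) {
      out$decay_defined <- FALSE          # constant turnover: r undefined
    } else {
      mt <- with_seed(derive_seed(seed, "mantel"),
                      vegan::mantel(stats::as.dist(turn), stats::as.dist(geo),
                                    permutations = n_iter))
      out$mantel_r <- unname(mt$statistic)
      out$mantel_p <- mt$signif
      out$decay_defined <- TRUE
    }
  }
  class(out) <- "phylobeta_result"
  out
}

#' @export
print.phylobeta_result <- function(x, ...) {
  cat("phylobeta_result:", nrow(x$pairs), "site pairs;",
      sum(x$pairs$pattern == "clustered"), "clustered\n")
  if (x$decay_defined)
    cat(sprintf("  distance decay: Mantel r = %.3f, p = %.4g\n",
                x$mantel_r, x$mantel_p))
  invisible(x)
}
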