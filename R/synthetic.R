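## Synthetic-data generators: trees, conserved/labile traits, communities
## assembled under known mechanisms, gradients and seasonal climates. These
## supply every input format the pipeline reads, with the statistical
## structure the analysis assumes, so calibration and power runs need no
## external data.

#' Simulate an ultrametric tree
#'
#' Birth-death (or pure-birth Yule) tree conditioned on the number of tips,
#' rescaled to a requested root depth. Tips are labelled `sp0001`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param model `"yule"` or `"birth_death"`.
#' @param birth,death speciation/extinction rates (birth > death >= 0;
#'   death forced to 0 for `"yule"`).
#' @param depth root-to-tip depth to rescale to (e.g. Myr); `NULL` keeps
#'   the simulated scale.
#' @param seed optional integer seed.
#' @return an ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "birth_death"),
                          birth = 1, death = 0, depth = NULL, seed = NULL) {
  model <- match.arg(model)
  if (model == "yule") death <- 0
  if (n_tips < 2) stop("need at least 2 tips")
  if (!(birth > death && death >= 0)) stop("require birth > death >= 0")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  if (!is.null(depth)) {
    cur <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / cur
  }
  tr$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tr
}

#' Evolve a continuous trait on a tree
#'
#' Brownian motion from a root value of 0 (tip variance sigma2 x root-tip
#' path length, covariance the shared path) for conserved traits, or
#' i.i.d. white noise for the labile alternative.
#'
#' @param tree a `phylo` with branch lengths (Brownian).
#' @param model `"brownian"` or `"white_noise"`.
#' @param sigma2 rate / variance (>= 0).
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
evolve_continuous_trait <- function(tree, model = c("brownian", "white_noise"),
                                    sigma2 = 1, seed = NULL) {
  model <- match.arg(model)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  n <- ape::Ntip(tree)
  with_seed(seed, {
    if (model == "white_noise") {
      x <- rnorm(n, 0, sqrt(sigma2))
      names(x) <- tree$tip.label
      x
    } else {
      if (is.null(tree$edge.length)) stop("Brownian motion needs branch lengths")
      x <- numeric(n + tree$Nnode)          # node values, root = 0
      edge <- ape::reorder.phylo(tree, "postorder")$edge
      elen <- ape::reorder.phylo(tree, "postorder")$edge.length
      for (i in rev(seq_len(nrow(edge))))   # preorder: parents before children
        x[edge[i, 2]] <- x[edge[i, 1]] + rnorm(1, 0, sqrt(sigma2 * elen[i]))
      out <- x[seq_len(n)]
      names(out) <- tree$tip.label
      out
    }
  })
}

#' Evolve a categorical trait on a tree (equal-rates Markov model)
#'
#' Continuous-time Markov chain along branches: change events arrive at the
#' given rate and jump to one of the other k - 1 states uniformly; the root
#' state is uniform.
#'
#' @param tree a `phylo` with branch lengths.
#' @param states character vector of state names (k >= 2) or an integer k.
#' @param rate expected change events per unit branch length (>= 0).
#' @param seed optional integer seed.
#' @return named character vector of tip states; the realized number of
#'   state changes is in attribute `n_changes`.
#' @export
evolve_categorical_trait <- function(tree, states = 2, rate = 0.1,
                                     seed = NULL) {
  if (length(states) == 1 && is.numeric(states))
    states <- paste0("state", seq_len(states))
  k <- length(states)
  if (k < 2) stop("need at least 2 states")
  if (rate < 0) stop("rate must be >= 0")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  n <- ape::Ntip(tree)
  with_seed(seed, {
    s <- integer(n + tree$Nnode)
    s[n + 1L] <- sample.int(k, 1)
    edge <- ape::reorder.phylo(tree, "postorder")$edge
    elen <- ape::reorder.phylo(tree, "postorder")$edge.length
    changes <- 0L
    for (i in rev(seq_len(nrow(edge)))) {
      st <- s[edge[i, 1]]
      nev <- stats::rpois(1, rate * elen[i])
      for (e in seq_len(nev)) {
        st <- sample(setdiff(seq_len(k), st), 1)
        changes <- changes + 1L
      }
      s[edge[i, 2]] <- st
    }
    out <- states[s[seq_len(n)]]
    names(out) <- tree$tip.label
    attr(out, "n_changes") <- changes
    out
  })
}

#' Describe an assembly scenario
#'
#' @param mechanism one of `"neutral"`, `"filtering"`,
#'   `"limiting_similarity"`, `"hierarchical_competition"`,
#'   `"filtering+hierarchical"`.
#' @param richness target community richness (>= 2).
#' @param strength mechanism strength (>= 0; for
#'   `"filtering+hierarchical"`, length 2: filter then competition).
#' @param optimum filter optimum on the standardized beta trait (default 0).
#' @return list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(mechanism = c("neutral", "filtering",
                                            "limiting_similarity",
                                            "hierarchical_competition",
                                            "filtering+hierarchical"),
                              richness, strength = 1, optimum = 0) {
  mechanism <- match.arg(mechanism)
  if (richness < 2) stop("richness must be >= 2")
  if (any(strength < 0)) stop("strength must be >= 0")
  if (mechanism == "filtering+hierarchical" && length(strength) == 1)
    strength <- c(strength, strength)
  structure(list(mechanism = mechanism, richness = richness,
                 strength = strength, optimum = optimum),
            class = "assembly_scenario")
}

#' Assemble a community from the regional pool under a known mechanism
#'
#' Mechanisms act on designated standardized traits: abiotic filtering
#' draws species with weight exp(-(z_beta - optimum)^2 / (2 h^2)) on the
#' filter (beta) trait, with h = 1 / strength; hierarchical competition
#' with weight exp(c z_alpha) on the competitive (alpha) trait, c =
#' strength; limiting similarity accepts candidates sequentially, rejecting
#' with probability exp(-d_min / delta) where d_min is the distance to the
#' nearest accepted species on the alpha trait and delta = 1 / strength;
#' neutral draws uniformly. The combined regime multiplies the filtering
#' and competition weights.
#'
#' @param scenario an `assembly_scenario`.
#' @param pool_traits a `trait_table` for the pool (used for the designated
#'   traits).
#' @param filter_trait,competition_trait names of the designated beta and
#'   alpha traits; defaults to the first beta / first alpha trait.
#' @param seed optional integer seed.
#' @return character vector of selected species labels.
#' @export
assemble_community <- function(scenario, pool_traits,
                               filter_trait = NULL, competition_trait = NULL,
                               seed = NULL) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  std <- standardize_traits(pool_traits)
  sp <- trait_species(std)
  r <- scenario$richness
  if (r > length(sp)) stop("richness exceeds pool size")
  pick_trait <- function(role, given) {
    if (!is.null(given)) return(std$values[[given]])
    nm <- std$schema$trait[std$schema$role == role &
                             std$schema$kind == "continuous"][1]
    if (is.na(nm)) stop("no continuous ", role, " trait available")
    std$values[[nm]]
  }
  with_seed(seed, {
    switch(scenario$mechanism,
      neutral = sample(sp, r),
      filtering = {
        z <- pick_trait("beta", filter_trait)
        h <- 1 / scenario$strength[1]
        w <- exp(-(z - scenario$optimum)^2 / (2 * h^2))
        sample(sp, r, prob = w)
      },
      hierarchical_competition = {
        z <- pick_trait("alpha", competition_trait)
        w <- exp(scenario$strength[1] * z)
        sample(sp, r, prob = w)
      },
      `filtering+hierarchical` = {
        zb <- pick_trait("beta", filter_trait)
        za <- pick_trait("alpha", competition_trait)
        h <- 1 / scenario$strength[1]
        w <- exp(-(zb - scenario$optimum)^2 / (2 * h^2)) *
          exp(scenario$strength[2] * za)
        sample(sp, r, prob = w)
      },
      limiting_similarity = {
        z <- pick_trait("alpha", competition_trait)
        names(z) <- sp
        delta <- 1 / scenario$strength[1]
        accepted <- sample(sp, 1)
        remaining <- setdiff(sp, accepted)
        tries <- 0L
        while (length(accepted) < r) {
          tries <- tries + 1L
          if (tries > 1000L * r)
            stop("infeasible richness under limiting similarity")
          cand <- sample(remaining, 1)
          d_min <- min(abs(z[cand] - z[accepted]))
          if (runif(1) >= exp(-d_min / delta)) {
            accepted <- c(accepted, cand)
            remaining <- setdiff(remaining, cand)
          }
        }
        accepted
      })
  })
}

#' Generate a full synthetic gradient dataset
#'
#' One pool tree, Brownian traits (7 alpha + 4 beta by default), per-site
#' communities assembled under the given regimes, and a site environment
#' table in which two synthetic resource axes (water, nutrients) track the
#' regime strengths, plus site coordinates spanning the gradient.
#'
#' @param n_sites number of sites (default 8).
#' @param pool_size regional pool size (default 174).
#' @param richness per-site richness; default evenly spans 19-62.
#' @param regimes list of `assembly_scenario` (one per site), or a preset
#'   name: `"paper_mimic"` (stress declining along the gradient, stressful
#'   sites filtered + hierarchically competitive, benign end neutral) or
#'   `"neutral"` (all sites neutral).
#' @param n_alpha,n_beta numbers of alpha and beta continuous traits.
#' @param tree_depth pool tree depth (default 150, angiosperm-scale Myr).
#' @param sigma2 Brownian rate for all traits.
#' @param trait_cor within-role trait correlation (default 0.7): traits of
#'   a role share a common Brownian "syndrome" component, emulating the
#'   coordinated tolerance/competition syndromes of real floras; alpha and
#'   beta syndromes are independent given the phylogeny.
#' @param trait_model `"brownian"` (conserved, the default) or
#'   `"white_noise"` (labile sensitivity variant).
#' @param seed optional master seed.
#' @return list of class `gradient_dataset`: `tree`, `traits`
#'   (`trait_table`), `comm` (`community_matrix` with coordinates and
#'   environment metadata), `env` (site x variable data.frame), `regimes`.
#' @export
generate_gradient_dataset <- function(n_sites = 8, pool_size = 174,
                                      richness = NULL,
                                      regimes = "paper_mimic",
                                      n_alpha = 7, n_beta = 4,
                                      tree_depth = 150, sigma2 = 1,
                                      trait_cor = 0.7,
                                      trait_model = "brownian",
                                      seed = NULL) {
  if (is.null(richness))
    richness <- round(seq(19, 62, length.out = n_sites))
  stopifnot(length(richness) == n_sites)
  stress <- seq(1, 0, length.out = n_sites)
  if (is.character(regimes)) {
    regimes <- switch(regimes,
      paper_mimic = lapply(seq_len(n_sites), function(i) {
        if (stress[i] == 0) assembly_scenario("neutral", richness[i])
        else assembly_scenario("filtering+hierarchical", richness[i],
                               strength = c(3 * stress[i], 1.5 * stress[i]))
      }),
      neutral = lapply(seq_len(n_sites),
                       function(i) assembly_scenario("neutral", richness[i])),
      stop("unknown preset; available: paper_mimic, neutral"))
  }
  stopifnot(length(regimes) == n_sites)

  tree <- simulate_tree(pool_size, "yule", depth = tree_depth,
                        seed = derive_seed(seed, "tree"))
  nm_a <- paste0("alpha_trait", seq_len(n_alpha))
  nm_b <- paste0("beta_trait", seq_len(n_beta))
  stopifnot(trait_cor >= 0, trait_cor < 1)
  role_block <- function(n, tag) {
    syndrome <- evolve_continuous_trait(
      tree, trait_model, sigma2, seed = derive_seed(seed, paste0("syn_", tag)))
    vapply(seq_len(n), function(t)
      sqrt(trait_cor) * syndrome + sqrt(1 - trait_cor) *
        evolve_continuous_trait(tree, trait_model, sigma2,
                                seed = derive_seed(seed, paste0(tag, t))),
      numeric(pool_size))
  }
  vals <- as.data.frame(cbind(role_block(n_alpha, "alpha"),
                              role_block(n_beta, "beta")))
  names(vals) <- c(nm_a, nm_b)
  rownames(vals) <- tree$tip.label
  schema <- data.frame(trait = c(nm_a, nm_b), kind = "continuous",
                       role = rep(c("alpha", "beta"), c(n_alpha, n_beta)),
                       states = NA_character_, ordered = FALSE,
                       stringsAsFactors = FALSE)
  traits <- trait_table(vals, schema)

  inc <- matrix(0L, n_sites, pool_size,
                dimnames = list(paste0("S", seq_len(n_sites)),
                                tree$tip.label))
  for (i in seq_len(n_sites)) {
    sel <- assemble_community(regimes[[i]], traits,
                              seed = derive_seed(seed, paste0("comm", i)))
    inc[i, sel] <- 1L
  }

  ## two partially independent resource axes: water availability follows
  ## the stress ladder; soil fertility overlays an alternating rich/poor
  ## profile (wet sites can sit on poor, sandy soil and vice versa)
  env <- with_seed(derive_seed(seed, "env"), {
    water <- (1 - stress) * 900 + 450 + rnorm(n_sites, 0, 40)
    fert <- (1 - stress) * 0.4 + rep(c(0.15, 0.85), length.out = n_sites) * 0.6
    nutrients <- fert * 8 + 2 + rnorm(n_sites, 0, 0.6)
    data.frame(
      rainfall = water,
      water_deficit = pmax(0, 1500 - water + rnorm(n_sites, 0, 50)),
      cec = nutrients,
      organic_matter = nutrients * 2.5 + rnorm(n_sites, 0, 2),
      ph = 4.5 + nutrients * 0.15 + rnorm(n_sites, 0, 0.3),
      sand = 90 - nutrients * 3 + rnorm(n_sites, 0, 5),
      row.names = paste0("S", seq_len(n_sites)))
  })
  meta <- data.frame(latitude = seq(-6.7, -3.8, length.out = n_sites),
                     longitude = seq(-40.1, -40.9, length.out = n_sites),
                     altitude = round(seq(300, 845, length.out = n_sites)),
                     env)
  comm <- community_matrix(inc, metadata = meta)
  structure(list(tree = tree, traits = traits, comm = comm, env = env,
                 regimes = regimes),
            class = "gradient_dataset")
}

#' @export
print.gradient_dataset <- function(x, ...) {
  cat("gradient_dataset:", nrow(x$comm$incidence), "sites,",
      ape::Ntip(x$tree), "pool species,", nrow(x$traits$schema), "traits\n")
  invisible(x)
}

#' Generate a seasonal semi-arid monthly climate series
#'
#' Rainfall is concentrated in a 3-4 month wet season (circular
#' concentration around a peak month) with truncated Gaussian noise on
#' monthly totals; temperature sits near 26 deg C with mild seasonality.
#' Presets follow the span of annual totals the gradient covers: `"arid"`
#' (474 mm) and `"subhumid"` (1383 mm).
#'
#' @param regime `"arid"` or `"subhumid"`.
#' @param annual_rainfall override the preset annual total (mm, > 0).
#' @param latitude site latitude (default -4).
#' @param peak_month wettest month (default 3).
#' @param concentration wet-season concentration (larger = more peaked).
#' @param noise_sd SD of multiplicative monthly noise (default 0.1).
#' @param site site label.
#' @param whc water holding capacity (mm).
#' @param seed optional integer seed.
#' @return a `climate_series`.
#' @export
generate_climate <- function(regime = c("arid", "subhumid"),
                             annual_rainfall = NULL, latitude = -4,
                             peak_month = 3, concentration = 2.5,
                             noise_sd = 0.1, site = regime[1], whc = 100,
                             seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(annual_rainfall))
    annual_rainfall <- switch(regime, arid = 474, subhumid = 1383)
  if (annual_rainfall <= 0) stop("annual rainfall must be positive")
  m <- 1:12
  w <- exp(concentration * cos(2 * pi * (m - peak_month) / 12))
  w <- w / sum(w)
  with_seed(seed, {
    rain <- annual_rainfall * w * pmax(0, 1 + rnorm(12, 0, noise_sd))
    temp <- 26 + 1.5 * cos(2 * pi * (m - 7) / 12) +
      rnorm(12, 0, 0.2)
    climate_series(site, latitude, temp, rain, whc)
  })
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Generates a gradient dataset plus per-site climates and writes the
#' newick tree, trait values + schema CSVs, community CSV, long-format
#' climate CSV and environment CSV into a directory. Deterministic under a
#' fixed seed.
#'
#' @param preset `"paper_mimic"` or `"neutral"` (see
#'   [generate_gradient_dataset()]).
#' @param outdir output directory (created if needed).
#' @param seed optional master seed.
#' @param ... passed to [generate_gradient_dataset()].
#' @return named character vector of the files written, invisibly; the
#'   dataset itself in attribute `dataset`.
#' @export
simulate_dataset <- function(preset = "paper_mimic", outdir, seed = NULL,
                             ...) {
  ds <- generate_gradient_dataset(regimes = preset, seed = seed, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(outdir, "tree.nwk"),
             traits = file.path(outdir, "traits.csv"),
             schema = file.path(outdir, "trait_schema.csv"),
             community = file.path(outdir, "community.csv"),
             climate = file.path(outdir, "climate.csv"),
             environment = file.path(outdir, "environment.csv"))
  write_newick(ds$tree, paths["tree"])
  write_trait_table(ds$traits, paths["traits"], paths["schema"])
  write_community_matrix(ds$comm, paths["community"])
  n_sites <- nrow(ds$comm$incidence)
  stress <- seq(1, 0, length.out = n_sites)
  clim <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    cs <- generate_climate(
      regime = if (stress[i] > 0.5) "arid" else "subhumid",
      annual_rainfall = ds$env$rainfall[i],
      latitude = ds$comm$metadata$latitude[i],
      site = rownames(ds$comm$incidence)[i],
      seed = derive_seed(seed, paste0("climate", i)))
    data.frame(site = cs$site, latitude = cs$latitude, month = 1:12,
               temperature = cs$temperature, rainfall = cs$rainfall)
  }))
  write.csv(clim, paths["climate"], row.names = FALSE)
  write.csv(cbind(site = rownames(ds$env), ds$env), paths["environment"],
            row.names = FALSE)
  attr(paths, "dataset") <- ds
  invisible(paths)
}
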