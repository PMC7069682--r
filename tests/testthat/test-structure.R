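test_that("mpd equals hand values and a naive pair-loop oracle", {
  tr <- ape::read.tree(text = "((A:5,B:5):5,(C:5,D:5):5);")
  d <- cophenetic_distances(tr)
  expect_equal(mpd(c("A", "B"), d), 10)
  expect_equal(mpd(c("A", "B", "C"), d), (10 + 20 + 20) / 3)
  expect_error(mpd("A", d), "at least 2")

  set.seed(21)
  for (rep in 1:40) {
    tree <- ape::rtree(30)
    dd <- cophenetic_distances(tree)
    sp <- sample(tree$tip.label, 15)
    expect_equal(mpd(sp, dd), naive_mpd(sp, dd), tolerance = 1e-12)
  }
})

test_that("adding a maximally distant species strictly increases mpd", {
  set.seed(22)
  for (rep in 1:10) {
    d <- random_dist(12, rep + 100)
    far <- "far"
    d2 <- rbind(cbind(d, far = max(d) + 5), far = c(rep(max(d) + 5, 12), 0))
    rownames(d2)[13] <- "far"
    sp <- sample(rownames(d), 6)
    expect_gt(mpd(c(sp, "far"), d2), mpd(sp, d2))
  }
})

test_that("phylogeny.pool null draws at observed richness from the pool", {
  tr <- ape::rtree(20)
  d <- cophenetic_distances(tr)
  pool <- tr$tip.label

  nd <- phylogeny_pool_null(5, pool, d, n_iter = 999, seed = 1)
  expect_length(nd$values, 999)
  expect_equal(nd$algorithm, "phylogeny.pool")

  # richness = pool size: every draw is the whole pool (degenerate)
  nd2 <- phylogeny_pool_null(20, pool, d, n_iter = 49, seed = 2)
  expect_true(nd2$degenerate)
  expect_equal(unique(nd2$values), mpd(pool, d))

  # richness-2 null mean equals the exact mean over all C(n,2) pairs
  exact <- mean(d[upper.tri(d)])
  nd3 <- phylogeny_pool_null(2, pool, d, n_iter = 5000, seed = 3)
  mc_se <- sd(nd3$values) / sqrt(5000)
  expect_lt(abs(mean(nd3$values) - exact), 4 * mc_se)

  expect_error(phylogeny_pool_null(21, pool, d), "exceeds pool")
})

test_that("ses follows the printed formula with mid-p and shape gating", {
  set.seed(4)
  null <- rnorm(999, 10, 2)
  s <- ses(10, null)
  expect_equal(s$ses, (10 - mean(null)) / sd(null), tolerance = 1e-9)
  expect_equal(s$pattern, "random")
  expect_false(s$corrected)

  # observed below all null values: p = 1/1000, clustered
  s2 <- ses(min(null) - 1, null)
  expect_equal(s2$p, 1 / 1000)
  expect_equal(s2$pattern, "clustered")

  # observed at mean + 2 SD of a normal null: SES ~ 2, p ~ 0.977
  big <- rnorm(200000, 0, 1)
  s3 <- ses(mean(big) + 2 * sd(big), big)
  expect_equal(s3$ses, 2, tolerance = 1e-6)
  expect_equal(s3$p, pnorm(2), tolerance = 0.005)
  expect_equal(s3$pattern, "overdispersed")

  # skewed null triggers the probit correction
  skewed <- rexp(999)
  s4 <- ses(1, skewed)
  expect_true(s4$corrected)
  expect_equal(s4$ses_corrected, qnorm(s4$p), tolerance = 1e-12)

  expect_error(ses(1, rep(2, 99)), "degenerate")
})

test_that("pattern classification applies the printed thresholds exactly", {
  expect_equal(classify_pattern(0.025), "clustered")
  expect_equal(classify_pattern(0.0251), "random")
  expect_equal(classify_pattern(0.975), "overdispersed")
  expect_equal(classify_pattern(0.9749), "random")
  expect_error(classify_pattern(0.5, lower = 0.6))
})

test_that("run_structure_analysis returns the four-metric table per site", {
  ds <- generate_gradient_dataset(n_sites = 3, pool_size = 40,
                                  richness = c(8, 10, 12), seed = 5)
  res <- run_structure_analysis(ds$comm, ds$tree, ds$traits, n_iter = 199,
                                seed = 6)
  expect_equal(nrow(res), 12)
  expect_setequal(unique(res$metric), c("mpd", "pw", "pw_alpha", "pw_beta"))
  expect_true(all(res$null_sd > 0))
  # SES identity holds wherever the raw SES is reported uncorrected
  expect_equal(res$ses, (res$observed - res$null_mean) / res$null_sd,
               tolerance = 1e-9)
  # deterministic under the same seed
  res2 <- run_structure_analysis(ds$comm, ds$tree, ds$traits, n_iter = 199,
                                 seed = 6)
  expect_equal(res$p, res2$p)

  # null distributions dump for shape diagnostics
  nd_dir <- withr::local_tempdir()
  run_structure_analysis(ds$comm, ds$tree, ds$traits, n_iter = 49,
                         seed = 6, null_out = nd_dir)
  dump <- read.csv(file.path(nd_dir, "null_S1.csv"))
  expect_equal(dim(dump), c(49, 4))
})

test_that("between-community mpd equals the inter-pair oracle", {
  tr <- ape::rtree(12)
  d <- cophenetic_distances(tr)
  expect_equal(between_community_mpd("t1", "t1", d), 0)
  expect_equal(between_community_mpd("t1", "t2", d), d["t1", "t2"])

  set.seed(31)
  for (rep in 1:40) {
    a <- sample(tr$tip.label, sample(2:6, 1))
    b <- sample(tr$tip.label, sample(2:6, 1))
    expect_equal(between_community_mpd(a, b, d), naive_between_mpd(a, b, d),
                 tolerance = 1e-12)
  }
  expect_error(between_community_mpd(character(0), "t1", d), "empty site")
})

test_that("phylobeta analysis flags constant turnover and finds real decay", {
  # identical composition at all sites: turnover 0, decay undefined
  tr <- ape::rtree(10)
  inc <- matrix(1L, 3, 10, dimnames = list(paste0("S", 1:3), tr$tip.label))
  md <- data.frame(latitude = c(-4, -5, -6), longitude = c(-40, -40, -40))
  pb <- phylobeta_analysis(community_matrix(inc, md), tr, n_iter = 99,
                           seed = 1)
  expect_true(all(pb$pairs$turnover == 0))
  expect_false(pb$decay_defined)

  # two compositional clusters matched to geography: positive Mantel r
  tr2 <- simulate_tree(40, "yule", depth = 100, seed = 7)
  clade <- ape::extract.clade(tr2, 42)$tip.label
  if (length(clade) < 8 || length(clade) > 32)
    clade <- tr2$tip.label[1:20]
  other <- setdiff(tr2$tip.label, clade)
  inc2 <- matrix(0L, 6, 40, dimnames = list(paste0("S", 1:6),
                                            tr2$tip.label))
  set.seed(8)
  for (i in 1:3) inc2[i, sample(clade, min(8, length(clade)))] <- 1L
  for (i in 4:6) inc2[i, sample(other, min(8, length(other)))] <- 1L
  md2 <- data.frame(latitude = c(-4, -4.1, -4.2, -8, -8.1, -8.2),
                    longitude = rep(-40, 6))
  pb2 <- phylobeta_analysis(community_matrix(inc2, md2), tr2, n_iter = 199,
                            seed = 9)
  expect_true(pb2$decay_defined)
  expect_gt(pb2$mantel_r, 0)
  expect_lte(pb2$mantel_p, 0.05)
})

test_that("mpd and the pool null agree with the picante reference", {
  tr <- simulate_tree(40, "yule", depth = 100, seed = 71)
  d <- cophenetic_distances(tr)
  comm <- matrix(0L, 3, 40, dimnames = list(paste0("S", 1:3), tr$tip.label))
  set.seed(72)
  for (i in 1:3) comm[i, sample(40, 12)] <- 1L

  ref_mpd <- picante::mpd(comm, d)
  mine <- vapply(1:3, function(i)
    mpd(colnames(comm)[comm[i, ] == 1], d), numeric(1))
  expect_equal(mine, ref_mpd, tolerance = 1e-12)

  # null distribution agrees statistically with picante's phylogeny.pool
  set.seed(73)
  ref <- picante::ses.mpd(comm, d, null.model = "phylogeny.pool",
                          runs = 499)
  nd <- phylogeny_pool_null(12, tr$tip.label, d, n_iter = 499, seed = 74)
  se <- sd(nd$values) / sqrt(499)
  for (i in 1:3)
    expect_lt(abs(mean(nd$values) - ref$mpd.rand.mean[i]), 5 * se)
  expect_lt(abs(sd(nd$values) - mean(ref$mpd.rand.sd)),
            0.2 * sd(nd$values))
})
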