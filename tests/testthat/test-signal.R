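test_that("independent contrasts match closed forms and hand recursion", {
  # two tips: (x1 - x2) / sqrt(v1 + v2)
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(pic_contrasts(tr, c(A = 3, B = 1)), 2 / sqrt(2))

  # identical values -> all contrasts zero
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(pic_contrasts(tr4, c(A = 2, B = 2, C = 2, D = 2)),
               rep(0, 3))

  # balanced 4-tip tree, unit lengths, values 1..4; hand-run recursion:
  # cherries: (1-2)/sqrt(2), (3-4)/sqrt(2); node values 1.5, 3.5 with
  # extended variance 1 + 1/2 each; root contrast (1.5-3.5)/sqrt(3)
  got <- sort(abs(pic_contrasts(tr4, c(A = 1, B = 2, C = 3, D = 4))))
  expect_equal(got, sort(abs(c(-1 / sqrt(2), -1 / sqrt(2), -2 / sqrt(3)))),
               tolerance = 1e-12)

  expect_error(pic_contrasts(tr4, c(A = 1, B = 2, C = 3)), "missing tip")
})

test_that("contrasts match ape::pic and are permutation-invariant", {
  set.seed(5)
  for (rep in 1:10) {
    tr <- ape::rtree(15)
    x <- setNames(rnorm(15), tr$tip.label)
    mine <- sort(abs(pic_contrasts(tr, x)))
    ref <- sort(abs(ape::pic(x[tr$tip.label], tr)))
    expect_equal(mine, unname(ref), tolerance = 1e-9)
    expect_length(mine, 14)
    # shuffling tip order of the input vector changes nothing
    perm <- sample(names(x))
    expect_equal(sort(abs(pic_contrasts(tr, x[perm]))), mine,
                 tolerance = 1e-12)
  }
})

test_that("continuous signal test ranks observed against tip shuffles", {
  # perfectly clade-sorted trait on a comb: observed far below null
  tr <- simulate_tree(32, "yule", depth = 50, seed = 2)
  x <- evolve_continuous_trait(tr, "brownian", 1, seed = 3)
  res <- continuous_signal_test(tr, x, n_iter = 999, seed = 4)
  expect_true(res$p <= 0.025)
  expect_lt(res$observed, res$null_mean)

  # rank formula floor: observed below every null value -> 1/(n_iter+1)
  expect_gte(res$p, 1 / 1000)

  # mean-absolute variant is available and consistent in direction
  res2 <- continuous_signal_test(tr, x, n_iter = 199, seed = 4,
                                 stat = "mean_abs")
  expect_lt(res2$observed, res2$null_mean)
})

test_that("fitch counts equal exhaustive enumeration on random trees", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  expect_equal(fitch_changes(tr, c(A = "x", B = "x", C = "y", D = "y")), 1L)
  expect_equal(fitch_changes(tr, c(A = "x", B = "x", C = "x", D = "x")), 0L)

  set.seed(7)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(letters[1:3], n, replace = TRUE),
                       tree$tip.label)
    expect_equal(fitch_changes(tree, states), brute_fitch(tree, states))
  }
  # polytomies: Hartigan rule still exact against enumeration
  for (rep in 1:20) {
    tree <- ape::di2multi(ape::rtree(7), tol = 0.4)
    states <- setNames(sample(c("a", "b"), 7, replace = TRUE),
                       tree$tip.label)
    expect_equal(fitch_changes(tree, states), brute_fitch(tree, states))
  }
})

test_that("fitch counts match phangorn parsimony and obey bounds", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    tree <- ape::rtree(n)
    states <- setNames(sample(c("a", "b", "c"), n, replace = TRUE),
                       tree$tip.label)
    obs <- fitch_changes(tree, states)
    dat <- phangorn::phyDat(matrix(states[tree$tip.label], ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c("a", "b", "c"))
    expect_equal(obs, unname(phangorn::parsimony(tree, dat)))
    expect_gte(obs, 0)
    expect_lte(obs, n - 1)
    if (length(unique(states)) == 1) expect_equal(obs, 0L)
    # binary bound: never exceeds the minority-state tip count
    b <- setNames(sample(c("a", "b"), n, replace = TRUE), tree$tip.label)
    expect_lte(fitch_changes(tree, b), min(table(factor(b, c("a", "b")))) +
                 as.integer(length(unique(b)) == 1))
  }
})

test_that("categorical signal test handles sorted and degenerate traits", {
  # perfectly clade-sorted binary trait: observed 1, below any shuffle
  tr <- simulate_tree(32, "yule", depth = 50, seed = 12)
  # pick an internal node whose clade splits the tips 8:24 to 24:8
  sizes <- vapply(33:63, function(nd)
    length(ape::extract.clade(tr, nd)$tip.label), integer(1))
  node <- (33:63)[which(sizes >= 8 & sizes <= 24)[1]]
  left <- ape::extract.clade(tr, node)$tip.label
  states <- setNames(ifelse(tr$tip.label %in% left, "x", "y"),
                     tr$tip.label)
  res <- categorical_signal_test(tr, states, n_iter = 999, seed = 13)
  expect_equal(unname(res$observed), 1)
  expect_equal(res$p, 1 / 1000)

  # monomorphic trait: observed 0, all null 0, p = 1
  mono <- setNames(rep("x", 32), tr$tip.label)
  resm <- categorical_signal_test(tr, mono, n_iter = 99, seed = 1)
  expect_equal(unname(resm$observed), 0)
  expect_equal(resm$p, 1)
})

test_that("signal_table runs every trait of a mixed table", {
  tr <- simulate_tree(12, "yule", depth = 50, seed = 30)
  tt <- paper_like_traits(n = 12, seed = 31)
  rownames(tt$values) <- tr$tip.label
  tt <- trait_table(tt$values, tt$schema)
  tab <- signal_table(tr, tt, n_iter = 99, seed = 32)
  expect_equal(nrow(tab), 11)
  expect_setequal(unique(tab$kind), c("continuous", "categorical"))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  # deterministic under the same seed
  tab2 <- signal_table(tr, tt, n_iter = 99, seed = 32)
  expect_equal(tab$p, tab2$p)
})
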