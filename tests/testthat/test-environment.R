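test_that("thornthwaite PET matches the published formulas", {
  # freezing months evaporate nothing
  cs <- climate_series("s", 0, temperature = rep(0, 12),
                       rainfall = rep(10, 12))
  expect_equal(thornthwaite_pet(cs), rep(0, 12))

  # constant 26 C at the equator: April (30 days) has day-length factor 1,
  # so PET_Apr equals the unadjusted formula value computed independently
  cs2 <- climate_series("s", 0, temperature = rep(26, 12),
                        rainfall = rep(0, 12))
  pet <- thornthwaite_pet(cs2)
  I <- 12 * (26 / 5)^1.514
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  expect_equal(pet[4], 16 * (10 * 26 / I)^a, tolerance = 1e-9)

  # hot-month polynomial above 26.5 C
  cs3 <- climate_series("s", 0, temperature = rep(30, 12),
                        rainfall = rep(0, 12))
  pet3 <- thornthwaite_pet(cs3)
  expect_equal(pet3[4], -415.85 + 32.24 * 30 - 0.43 * 900, tolerance = 1e-9)

  # monotone in one month's temperature, all else fixed
  petT <- vapply(seq(1, 26, by = 1), function(Tm) {
    temps <- rep(20, 12); temps[4] <- Tm
    thornthwaite_pet(climate_series("s", 0, temps, rep(0, 12)))[4]
  }, numeric(1))
  expect_true(all(diff(petT) > 0))

  expect_error(climate_series("s", 70, rep(20, 12), rep(0, 12)),
               "latitude")
})

test_that("water balance conserves water and respects storage bounds", {
  for (seed in 1:6) {
    regime <- if (seed %% 2) "arid" else "subhumid"
    wb <- water_balance(generate_climate(regime, seed = seed))
    a <- attr(wb, "annual")
    expect_lt(abs(a["rainfall"] - a["aet"] - a["exc"]), 0.05)
    expect_true(all(wb$def >= -1e-9))
    expect_true(all(wb$aet <= wb$pet + 1e-9))
    expect_true(all(wb$gw >= 0 & wb$gw <= 100 + 1e-9))
    expect_equal(wb$alt, wb$gw - wb$gw[c(12, 1:11)], tolerance = 1e-9)
  }
})

test_that("equilibrium climate yields a flat ledger", {
  cs <- climate_series("s", -4, temperature = rep(20, 12),
                       rainfall = rep(1, 12))
  pet <- thornthwaite_pet(cs)
  cs$rainfall <- pet                        # R = PET exactly, every month
  wb <- water_balance(cs, pet = pet)
  expect_equal(wb$def, rep(0, 12), tolerance = 1e-9)
  expect_equal(wb$exc, rep(0, 12), tolerance = 1e-9)
  expect_equal(wb$aet, pet, tolerance = 1e-9)
  expect_equal(sd(wb$gw), 0)
})

test_that("rainless year decays storage exponentially toward zero", {
  cs <- climate_series("s", -4, temperature = rep(25, 12),
                       rainfall = rep(0, 12))
  wb <- water_balance(cs)
  expect_equal(attr(wb, "branch"), "pereira_arid")
  expect_equal(wb$gw, 100 * exp(wb$neg / 100), tolerance = 1e-6)
  expect_lt(max(wb$aet), 1e-3)
  expect_equal(sum(wb$def), sum(wb$pet), tolerance = 0.01)
})

test_that("arid preset triggers the simplified arid branch, wet does not", {
  arid <- water_balance(generate_climate("arid", seed = 1))
  expect_equal(attr(arid, "branch"), "pereira_arid")
  a <- attr(arid, "annual")
  expect_lt(a["rainfall"], a["pet"])       # PET >> R on ~474 mm
  expect_equal(unname(a["exc"]), 0)

  wet <- water_balance(generate_climate("subhumid", seed = 1))
  expect_equal(attr(wet, "branch"), "standard")
  expect_gt(sum(wet$exc), 0)               # wet months spill
})

test_that("collinearity filter drops the right variables", {
  set.seed(41)
  x <- data.frame(a = rnorm(30))
  x$b <- x$a                                # perfect copy
  x$c <- rnorm(30)
  kept <- suppressWarnings(collinearity_filter(x, 0.7))
  expect_true("c" %in% kept)
  expect_equal(sum(c("a", "b") %in% kept), 1)

  y <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  expect_setequal(collinearity_filter(y, 0.99), names(y))

  z <- cbind(y, k = 1)
  expect_warning(collinearity_filter(z, 0.7), "constant")

  # constructed 5-variable case: v1 correlated with v2 and v3; dropping v1
  # suffices, matching the minimal-drop solution
  set.seed(42)
  v1 <- rnorm(200)
  w <- data.frame(v1 = v1,
                  v2 = 0.8 * v1 + 0.6 * rnorm(200),
                  v3 = 0.8 * v1 + 0.6 * rnorm(200),
                  v4 = rnorm(200), v5 = rnorm(200))
  stopifnot(abs(cor(w$v1, w$v2)) >= 0.7, abs(cor(w$v1, w$v3)) >= 0.7,
            abs(cor(w$v2, w$v3)) < 0.7)
  expect_setequal(collinearity_filter(w, 0.7), c("v2", "v3", "v4", "v5"))
  r <- abs(cor(w[collinearity_filter(w, 0.7)]))
  expect_true(all(r[upper.tri(r)] < 0.7))
})

test_that("broken-stick PCA retains axes beyond the null expectation", {
  # closed form for p = 2
  set.seed(43)
  x2 <- data.frame(a = rnorm(20), b = rnorm(20))
  pc2 <- pca_broken_stick(x2)
  expect_equal(pc2$broken_stick, c(0.75, 0.25))
  expect_equal(sum(pc2$proportion), 1, tolerance = 1e-9)
  expect_true(all(diff(pc2$eigenvalues) <= 1e-12))

  # duplicated variable pair: axis 1 carries all their shared variance
  x3 <- data.frame(a = rnorm(20))
  x3$b <- x3$a * 2 + 3
  pc3 <- pca_broken_stick(x3)
  expect_equal(abs(unname(pc3$correlations[c("a", "b"), 1])), c(1, 1),
               tolerance = 1e-6)
  expect_true(pc3$significant[1])
  expect_equal(pc3$proportion[1], 1, tolerance = 1e-9)
})

test_that("gradient regression recovers exact and noisy slopes", {
  set.seed(44)
  g <- rnorm(12)
  env <- data.frame(g1 = g, g2 = g + 0.3 * rnorm(12),
                    g3 = g + 0.3 * rnorm(12),
                    row.names = paste0("S", 1:12))
  pca <- pca_broken_stick(env)
  stopifnot(pca$significant[1])
  ses_tab <- data.frame(site = rownames(env), metric = "mpd",
                        ses = 2 * pca$scores[, 1] + 1)
  if (sum(pca$significant) > 1)
    ses_tab$ses <- ses_tab$ses + 0.5 * pca$scores[, 2]
  gr <- suppressWarnings(gradient_regression(ses_tab, pca))  # exact fit
  expect_equal(gr$fit$r_squared, 1, tolerance = 1e-9)
  est <- gr$coefficients$estimate[gr$coefficients$term == "PC1"]
  expect_equal(est, 2, tolerance = 1e-9)

  # error when predictors outnumber sites - 2
  tiny <- data.frame(g1 = rnorm(3), g2 = rnorm(3), g3 = rnorm(3),
                     row.names = paste0("S", 1:3))
  pc_t <- pca_broken_stick(tiny)
  pc_t$significant <- rep(TRUE, length(pc_t$significant))
  st <- data.frame(site = paste0("S", 1:3), metric = "mpd", ses = rnorm(3))
  expect_error(gradient_regression(st, pc_t), "predictors")
})
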