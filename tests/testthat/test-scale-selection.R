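test_that("period-2 replicates collapse to the within-period maximum", {
  d <- survey_design(2, 1, 3, sites = c("A", "B"))
  arr <- array(NA_integer_, c(1, 2, 2, 2))
  arr[1, , 1, 1] <- c(2L, 7L)
  arr[1, , 2, ] <- c(3L, 0L, 5L, 0L)   # site A: (3,5); site B: (0,0)
  cts <- count_data(arr, d)
  resp <- collapse_period2_max(cts)
  expect_identical(resp[1, "A", 2], 5L)
  expect_identical(resp[1, "B", 2], 0L)
  expect_identical(resp[1, "A", 1], 2L)   # period 1 passes through
})

test_that("univariate Poisson fits match closed forms and recover slopes", {
  # constant response: slope zero, intercept log of the mean
  f <- fit_univariate(rep(3, 10), runif(10))
  expect_equal(f$eta, 0, tolerance = 1e-6)
  expect_equal(f$zeta, log(3), tolerance = 1e-6)

  # two points interpolated exactly on the log link
  f2 <- fit_univariate(c(1, exp(1)), c(0, 1))
  expect_equal(f2$zeta, 0, tolerance = 1e-8)
  expect_equal(f2$eta, 1, tolerance = 1e-8)

  # all-zero response is flagged degenerate, not fit
  f0 <- fit_univariate(rep(0, 5), runif(5))
  expect_true(f0$degenerate)
  expect_identical(f0$eta, 0)
  expect_identical(f0$zeta, -Inf)

  # MLE consistency at the generating slope
  set.seed(31)
  E <- runif(5000)
  y <- rpois(5000, exp(1 + 2 * E))
  f3 <- fit_univariate(y, E)
  expect_lt(abs(f3$eta - 2), 0.1)
})

test_that("leave-one-out predictions equal per-fold refits", {
  # constant response predicts itself in every fold
  expect_equal(loo_predictions(rep(4, 6), runif(6)), rep(4, 6))

  # oracle: brute-force per-fold glm refits
  set.seed(12)
  for (rep in 1:3) {
    n <- sample(3:12, 1)
    E <- runif(n)
    y <- rpois(n, exp(0.5 + 1.5 * E))
    if (sum(y) == 0) next
    pr <- loo_predictions(y, E)
    ref <- sapply(seq_len(n), function(f) {
      if (sum(y[-f]) == 0) return(NA_real_)
      fit <- suppressWarnings(glm(y[-f] ~ E[-f], family = poisson()))
      unname(exp(coef(fit)[1] + coef(fit)[2] * E[f]))
    })
    expect_equal(pr, ref, tolerance = 1e-7)
  }

  # a fold whose training response is all zero is flagged missing
  y <- c(5, 0, 0, 0)
  pr <- loo_predictions(y, c(0.1, 0.4, 0.6, 0.9))
  expect_true(is.na(pr[1]))
  expect_false(anyNA(pr[-1]))

  # a fold with a constant training covariate is flagged missing
  pr2 <- loo_predictions(c(1, 2, 3, 1), c(0.2, 0.5, 0.5, 0.5))
  expect_true(is.na(pr2[1]))
})

test_that("model enumeration bookkeeping is exact", {
  set.seed(7)
  for (rep in 1:5) {
    S <- sample(1:8, 1); M <- sample(1:5, 1); C <- sample(1:10, 1)
    d <- survey_design(4, S, M)
    g <- build_scale_grid(50, 50 * C, 50)
    plan <- scale_selection_plan(d, g)
    expect_identical(plan$n_models, S * M * C)
    expect_identical(plan$n_map_entries, S * M)
    expect_identical(nrow(plan$configurations), S * M * C)
  }
})

test_that("correlation selection returns the argmax radius with smallest-radius ties", {
  d <- tiny_design(n_sites = 20, n_species = 2)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 21)

  map <- select_scale_correlation(sim$counts, sim$stack)
  expect_identical(attr(map, "n_models"),
                   d$n_species * d$n_landcover * length(g$radii))
  expect_identical(nrow(map), d$n_species * d$n_landcover)
  # selected score is the maximum over radii
  sc <- attr(map, "scores")
  for (r in seq_len(nrow(map))) {
    i <- match(map$species[r], d$species)
    m <- match(map$type[r], d$types)
    if (!is.na(map$score[r]))
      expect_lte(max(sc[i, m, ], na.rm = TRUE), map$score[r] + 1e-12)
  }

  # single-radius grid: that radius wins everywhere
  g1 <- build_scale_grid(100, 100, 50)
  arr1 <- sim$stack$proportions[, , 2, , drop = FALSE]
  stack1 <- landcover_stack(array(arr1, c(20, 3, 1, 2)), d, g1)
  map1 <- select_scale_correlation(sim$counts, stack1)
  expect_true(all(map1$radius == 100))

  # duplicated radii tie exactly: the smallest wins
  arr2 <- sim$stack$proportions
  arr2[, , 2, ] <- arr2[, , 1, ]
  stack2 <- landcover_stack(arr2, d, g)
  map2 <- select_scale_correlation(sim$counts, stack2)
  sc2 <- attr(map2, "scores")
  for (r in seq_len(nrow(map2))) {
    i <- match(map2$species[r], d$species)
    m <- match(map2$type[r], d$types)
    if (!is.na(sc2[i, m, 1]) && !is.na(sc2[i, m, 2]) &&
        sc2[i, m, 1] >= max(sc2[i, m, ], na.rm = TRUE) - 1e-12)
      expect_identical(map2$radius[r], 50)
  }
})

test_that("boosted trees find a single dominant predictor and are reproducible", {
  set.seed(42)
  d <- survey_design(n_sites = 120, n_species = 2, n_landcover = 3)
  g <- build_scale_grid(50, 500, 50)
  stack <- generate_landscape(d, g, seed = 5, spatial_smoothness = 0.5)
  cidx <- match(300, g$radii)
  E <- stack$proportions[, 2, cidx, ]   # lc2 at 300 m drives the response
  y <- array(NA_integer_, c(2, 120, 2, 2))
  for (t in 1:2)
    y[, , t, 1] <- matrix(rpois(2 * 120, exp(1 + 2.5 * rep(E[, t], each = 2))),
                          2, 120)
  y[, , 2, 2] <- y[, , 2, 1]
  cts <- count_data(y, d)
  st <- brt_settings(n_trees = 400, shrinkage = 0.1)

  m1 <- select_scale_brt(cts, stack, st, seed = 9)
  m2 <- select_scale_brt(cts, stack, st, seed = 9)
  expect_identical(m1$radius, m2$radius)   # same seed, same map

  infl <- attr(m1, "influence")
  for (i in 1:2) {
    top <- which(infl[i, , ] == max(infl[i, , ]), arr.ind = TRUE)
    expect_identical(unname(top[1, 1]), 2L)     # lc2
    expect_identical(unname(top[1, 2]), cidx)   # 300 m
  }
  expect_true(all(m1$radius[m1$type == "lc2"] == 300))
})

test_that("sparse species inherit the most similar species' scales", {
  set.seed(13)
  d <- survey_design(n_sites = 60, n_species = 3, n_landcover = 2)
  g <- build_scale_grid(50, 150, 50)
  stack <- generate_landscape(d, g, seed = 2)
  y <- array(NA_integer_, c(3, 60, 2, 2))
  base <- matrix(rpois(2 * 60, 4), 2, 60)
  for (t in 1:2) y[, , t, 1] <- rbind(base, 0L)
  y[, , 2, 2] <- y[, , 2, 1]
  cts <- count_data(y, d)   # sp03 never observed
  st <- brt_settings(n_trees = 100, shrinkage = 0.1)

  map <- select_scale_brt(cts, stack, st, seed = 3)
  sub <- map[map$species == "sp03", ]
  expect_true(all(!is.na(sub$donor)))
  donor <- unique(sub$donor)
  expect_length(donor, 1L)
  for (m in d$types)
    expect_identical(sub$radius[sub$type == m],
                     map$radius[map$species == donor & map$type == m])

  # an explicit donor mapping takes precedence
  map2 <- select_scale_brt(cts, stack, st, seed = 3,
                           donor_map = c(sp03 = "sp02"))
  expect_true(all(map2$donor[map2$species == "sp03"] == "sp02"))
})
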