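test_that("generated landscapes are closed compositions with coherent limits", {
  d <- tiny_design(n_sites = 15)
  g <- build_scale_grid(50, 500, 50)
  stack <- generate_landscape(d, g, seed = 3)
  sums <- apply(stack$proportions, c(1, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(stack$proportions >= 0 & stack$proportions <= 1))

  # infinitely smooth landscape: every radius repeats the innermost buffer
  flat <- generate_landscape(d, g, seed = 3, spatial_smoothness = 1e12)
  for (cc in seq_along(g$radii))
    expect_equal(flat$proportions[, , cc, 1], flat$proportions[, , 1, 1],
                 ignore_attr = TRUE)

  # no temporal shock: the two periods are identical
  still <- generate_landscape(d, g, seed = 3, shock_sd = 0)
  expect_identical(still$proportions[, , , 1], still$proportions[, , , 2])

  expect_error(generate_landscape(d, g, spatial_smoothness = 0), "smoothness")
})

test_that("community draws follow the stated hyperpriors", {
  g <- tiny_grid()
  # centre/concentration maps to the Beta shape pair: psi=0.4, theta=5 -> (2,3)
  hp <- community_hyperparams(3, psi = 0.4, theta = 5)
  d <- tiny_design(n_species = 4)
  com <- generate_community(d, g, hp, seed = 1)
  expect_equal(unname(com$beta_ab), c(2, 3))

  # vanishing tau pins every species' effect at the type mean
  hp0 <- community_hyperparams(3, mu = c(1, -2, 0.5), tau = 1e-9)
  com0 <- generate_community(d, g, hp0, seed = 1)
  expect_lt(max(abs(sweep(com0$beta, 2, c(1, -2, 0.5)))), 1e-6)

  # law of large numbers: detection probabilities centre on psi
  dbig <- survey_design(2, 10000, 3)
  comb <- generate_community(dbig, g, hp, seed = 2)
  se <- sqrt(0.4 * 0.6 / (5 + 1) / 10000)
  expect_lt(abs(mean(comb$detect_p) - 0.4), 4 * se)

  # generating scales live on the grid
  expect_true(all(com$true_scale %in% g$radii))
  fixed <- generate_community(d, g, hp, seed = 1, true_scale = 100)
  expect_true(all(fixed$true_scale == 100))
  expect_error(generate_community(d, g, hp, seed = 1, true_scale = 75),
               "radius of the grid")
})

test_that("count simulation reproduces the N-mixture structure", {
  d <- survey_design(n_sites = 30, n_species = 4, n_landcover = 3)
  g <- tiny_grid()
  stack <- generate_landscape(d, g, seed = 5, shock_sd = 0)
  com <- generate_community(d, g, seed = 5)

  # perfect detection: every replicate equals the latent truth
  com1 <- com; com1$detect_p[] <- 1
  sim <- simulate_counts(com1, stack, d, seed = 1)
  expect_identical(sim$counts$counts[, , 1, 1], sim$N[, , 1])
  expect_identical(sim$counts$counts[, , 2, 1], sim$N[, , 2])
  expect_identical(sim$counts$counts[, , 2, 2], sim$N[, , 2])

  # no drift + static landscape: stationary expected abundance
  com2 <- com; com2$phi[] <- 0
  sim2 <- simulate_counts(com2, stack, d, seed = 2)
  expect_equal(sim2$lambda[, , 1], sim2$lambda[, , 2], ignore_attr = TRUE)

  # the fixed50 variant rejects a nonzero intercept
  expect_error(simulate_counts(com, stack, d, model_variant = "fixed50"),
               "alpha")
})

test_that("latent abundance matches the Poisson mean oracle", {
  # oracle: closed-form Poisson mean exp(0.7), computed here independently
  d <- survey_design(n_sites = 10000, n_species = 1, n_landcover = 2)
  g <- build_scale_grid(50, 50, 50)
  arr <- array(c(rep(c(1, 0), each = 10000), rep(c(1, 0), each = 10000)),
               c(10000, 2, 1, 2))
  stack <- landcover_stack(arr, d, g)
  com <- generate_community(d, g, community_hyperparams(2), seed = 1)
  com$alpha[] <- 0
  com$beta[] <- c(0.7, 0)   # E concentrated on type 1 -> lambda = exp(0.7)
  com$phi[] <- 0
  sim <- simulate_counts(com, stack, d, seed = 7, model_variant = "fixed50")
  target <- exp(0.7)
  se <- sqrt(target / 10000)
  expect_lt(abs(mean(sim$N[, , 1]) - target), 4 * se)
})

test_that("replicate counts share the latent abundance", {
  d <- survey_design(n_sites = 400, n_species = 2, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 11)
  y1 <- as.vector(sim$counts$counts[, , 2, 1])
  y2 <- as.vector(sim$counts$counts[, , 2, 2])
  expect_gt(cor(y1, y2), 0)
})

test_that("single-replicate counts are marginally Poisson(lambda * p)", {
  lam <- 3; p <- 0.6
  n <- 2000
  rejections <- 0
  for (s in 1:50) {
    set.seed(s)
    N <- rpois(n, lam)
    y <- rbinom(n, N, p)
    kmax <- max(y)
    probs <- dpois(0:kmax, lam * p)
    probs <- c(probs, 1 - sum(probs))
    obs <- tabulate(y + 1L, nbins = kmax + 1L)
    obs <- c(obs, 0)
    keep <- probs * n >= 5
    pval <- suppressWarnings(
      chisq.test(c(obs[keep], sum(obs[!keep])),
                 p = c(probs[keep], sum(probs[!keep])))$p.value)
    if (pval < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("identical hyperpriors make species exchangeable", {
  d <- survey_design(n_sites = 25, n_species = 4, n_landcover = 3)
  g <- tiny_grid()
  hp <- community_hyperparams(3, mu = c(1, 0, -1), tau = 1e-9,
                              sigma = 1e-9, tau_alpha = 1e-9)
  means <- matrix(NA_real_, 30, 4)
  for (s in 1:30) {
    stack <- generate_landscape(d, g, seed = s)
    com <- generate_community(d, g, hp, seed = s)
    com$detect_p[] <- 0.5
    sim <- simulate_counts(com, stack, d, seed = s)
    means[s, ] <- rowMeans(sim$counts$counts[, , 1, 1])
  }
  df <- data.frame(y = as.vector(means), sp = factor(rep(1:4, each = 30)))
  p <- anova(lm(y ~ sp, df))[["Pr(>F)"]][1]
  expect_gt(p, 0.01)
})
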