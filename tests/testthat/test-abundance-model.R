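test_that("model fitting is deterministic under a fixed seed", {
  d <- survey_design(n_sites = 15, n_species = 3, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 4, model_variant = "fixed50")
  sp <- model_spec("fixed50", chains = 1, warmup = 100, sampling = 50,
                   adapt = 100)
  f1 <- fit_abundance_model(sim$counts, sim$stack, NULL, sp, seed = 5,
                            on_nonconvergence = "none")
  f2 <- fit_abundance_model(sim$counts, sim$stack, NULL, sp, seed = 5,
                            on_nonconvergence = "none")
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$N, f2$draws$N)
  f3 <- fit_abundance_model(sim$counts, sim$stack, NULL, sp, seed = 6,
                            on_nonconvergence = "none")
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("the multiscale variant demands a scale map and validates it", {
  d <- survey_design(n_sites = 10, n_species = 2, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 4)
  sp <- quick_spec("multiscale", chains = 1, warmup = 50, sampling = 30,
                   adapt = 50)
  expect_error(fit_abundance_model(sim$counts, sim$stack, NULL, sp),
               "scale_map")
  bad_map <- true_scale_map(sim$params, d)[-1, ]
  expect_error(fit_abundance_model(sim$counts, sim$stack, bad_map, sp),
               "one row per species")
})

test_that("posterior totals add up and track near-perfect detection", {
  d <- survey_design(n_sites = 40, n_species = 3, n_landcover = 3)
  g <- tiny_grid()
  hp <- community_hyperparams(3, mu = c(1.2, 0.5, 0.8), tau = 0.3,
                              psi = 0.97, theta = 60)
  stack <- generate_landscape(d, g, seed = 9)
  com <- generate_community(d, g, hp, seed = 9)
  com$alpha[] <- 0
  com$detect_p[] <- 1
  sim <- simulate_counts(com, stack, d, seed = 9, model_variant = "fixed50")
  sp <- model_spec("fixed50", chains = 2, warmup = 500, sampling = 300,
                   adapt = 200)
  fit <- fit_abundance_model(sim$counts, stack, NULL, sp, seed = 2,
                             on_nonconvergence = "none")
  post <- posterior_true_abundance(fit)

  # additivity: totals are exact sums of the per-site draws
  expect_equal(post$species_totals[, 2, 1],
               rowSums(fit$draws$N[, 2, , 1]))
  expect_equal(post$community_totals[, 1], rowSums(post$species_totals[, , 1]))

  # perfect-detection data: posterior species totals sit near observed totals
  obs <- rowSums(sim$counts$counts[, , 1, 1])
  med <- apply(post$species_totals[, , 1], 2, median)
  expect_lt(max(abs(med - obs) / pmax(obs, 1)), 0.15)
})

test_that("species relabelling leaves posterior summaries unchanged", {
  d <- survey_design(n_sites = 25, n_species = 3, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 14, model_variant = "fixed50")
  sp <- model_spec("fixed50", chains = 2, warmup = 600, sampling = 400,
                   adapt = 200)
  fit <- fit_abundance_model(sim$counts, sim$stack, NULL, sp, seed = 3,
                             on_nonconvergence = "none")
  perm <- c(3L, 1L, 2L)
  dperm <- survey_design(25, 3, 3, species = d$species[perm])
  cperm <- count_data(sim$counts$counts[perm, , , ], dperm)
  stack_p <- landcover_stack(sim$stack$proportions, dperm, g)
  fitp <- fit_abundance_model(cperm, stack_p, NULL, sp, seed = 3,
                              on_nonconvergence = "none")
  medP <- apply(fit$draws$P, 2, median)
  medPp <- apply(fitp$draws$P, 2, median)
  expect_equal(medPp, medP[perm], tolerance = 0.15)
  medB <- apply(fit$draws$beta, c(2, 3), median)
  medBp <- apply(fitp$draws$beta, c(2, 3), median)
  expect_lt(max(abs(medBp - medB[perm, ])), 0.8)
})

test_that("shrinking the pooling prior pulls species effects together", {
  d <- survey_design(n_sites = 30, n_species = 6, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 17, model_variant = "fixed50")
  spread <- sapply(c(1.0, 0.1, 0.01), function(s) {
    sp <- model_spec("fixed50", chains = 1, warmup = 400, sampling = 300,
                     adapt = 200, scale_scale = s)
    fit <- fit_abundance_model(sim$counts, sim$stack, NULL, sp, seed = 4,
                               on_nonconvergence = "none")
    betamed <- apply(fit$draws$beta, c(2, 3), median)
    mean(apply(betamed, 2, sd))
  })
  expect_true(all(diff(spread) < 0))
})

test_that("non-convergence fails loudly with a diagnostics table", {
  d <- survey_design(n_sites = 20, n_species = 3, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 4)
  map <- true_scale_map(sim$params, d)
  # intercept/effect near-collinearity at minimal chain length cannot converge
  sp <- model_spec("multiscale", chains = 2, warmup = 30, sampling = 40,
                   adapt = 50)
  err <- tryCatch(
    fit_abundance_model(sim$counts, sim$stack, map, sp, seed = 1),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "split-Rhat")
  expect_s3_class(err$rhat_table, "data.frame")
})

test_that("retrodiction intervals cover the data that generated them", {
  d <- survey_design(n_sites = 40, n_species = 4, n_landcover = 3)
  g <- tiny_grid()
  sim <- simulate_dataset(d, g, seed = 23, model_variant = "fixed50")
  sp <- model_spec("fixed50", chains = 2, warmup = 500, sampling = 300,
                   adapt = 200)
  fit <- fit_abundance_model(sim$counts, sim$stack, NULL, sp, seed = 7,
                             on_nonconvergence = "none")
  rc <- retrodiction_check(fit, seed = 1)
  expect_identical(nrow(rc), 8L)
  # a well-specified model retrodicts most observed totals
  expect_gte(mean(rc$inside), 0.85)
  # retrodiction is reproducible under the same seed
  expect_identical(rc, retrodiction_check(fit, seed = 1))
})

test_that("an unobserved species retrodicts totals near zero", {
  d <- survey_design(n_sites = 30, n_species = 3, n_landcover = 3)
  g <- tiny_grid()
  stack <- generate_landscape(d, g, seed = 3)
  com <- generate_community(d, g, seed = 3)
  com$alpha[] <- 0
  com$beta[3, ] <- -8      # effectively absent species
  sim <- simulate_counts(com, stack, d, seed = 3, model_variant = "fixed50")
  expect_true(all(sim$counts$counts[3, , , ] == 0, na.rm = TRUE))
  sp <- model_spec("fixed50", chains = 1, warmup = 300, sampling = 300,
                   adapt = 200)
  fit <- fit_abundance_model(sim$counts, stack, NULL, sp, seed = 2,
                             on_nonconvergence = "none")
  rc <- retrodiction_check(fit, seed = 5)
  sub <- rc[rc$species == "sp03", ]
  expect_true(all(sub$median <= 2))
})
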