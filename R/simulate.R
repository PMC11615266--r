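#' Default community hyperparameters
#'
#' Hyperparameters of the generating community: per-type means and spreads of
#' the log-scale habitat effects, the drift hyperprior, the intercept
#' hyperprior (multiscale variant), and the Beta detection hyperprior in its
#' centre/concentration parametrization (`a = psi * theta`,
#' `b = (1 - psi) * theta`).
#'
#' @param n_landcover number of land-cover types M.
#' @param mu,tau per-type mean and sd of species habitat effects beta.
#' @param rho,sigma mean and sd of the species drift term phi (log change in
#'   abundance not attributable to land cover).
#' @param mu_alpha,tau_alpha mean and sd of species intercepts (multiscale).
#' @param psi,theta centre and concentration of the Beta distribution of
#'   species detection probabilities; the default (0.4, 5) centres detection
#'   at 0.40 with Beta(2, 3) shape.
#' @return a named list of class `community_hyperparams`.
#' @export
community_hyperparams <- function(n_landcover,
                                  mu = rep(0, n_landcover),
                                  tau = rep(1, n_landcover),
                                  rho = 0, sigma = 0.5,
                                  mu_alpha = 0, tau_alpha = 1,
                                  psi = 0.4, theta = 5) {
  mu <- rep(mu, length.out = n_landcover)
  tau <- rep(tau, length.out = n_landcover)
  stopifnot(length(mu) == n_landcover, length(tau) == n_landcover,
            all(tau > 0), sigma > 0, tau_alpha > 0,
            psi > 0, psi < 1, theta > 0)
  structure(list(n_landcover = n_landcover, mu = mu, tau = tau, rho = rho,
                 sigma = sigma, mu_alpha = mu_alpha, tau_alpha = tau_alpha,
                 psi = psi, theta = theta),
            class = "community_hyperparams")
}

#' Draw community hyperparameters from the model's priors
#'
#' For calibration (coverage) experiments the generating hyperparameters are
#' drawn from the same priors the abundance model uses — Normal(0,
#' `loc_scale`) locations, half-Normal(0, `scale_scale`) scales, and the
#' Beta/Gamma detection hyperpriors — so that posterior credible intervals
#' have exactly their nominal frequentist coverage over replicate
#' simulations. Fit the model with matching `loc_scale` / `scale_scale` for
#' the calibration to be exact.
#'
#' @param n_landcover number of land-cover types.
#' @param seed integer seed.
#' @param loc_scale,scale_scale prior standard deviations (see
#'   [model_spec()]).
#' @param psi_prior,theta_prior detection hyperprior shape pairs.
#' @return a [community_hyperparams()] object.
#' @export
draw_hyperparams_from_priors <- function(n_landcover, seed = 1,
                                         loc_scale = 1, scale_scale = 1,
                                         psi_prior = c(2, 3),
                                         theta_prior = c(9, 5)) {
  set.seed(split_seed(seed, 14L))
  M <- n_landcover
  half <- function(n, s) pmax(abs(stats::rnorm(n, 0, s)), 1e-3)
  community_hyperparams(
    M,
    mu = stats::rnorm(M, 0, loc_scale), tau = half(M, scale_scale),
    rho = stats::rnorm(1, 0, loc_scale), sigma = half(1, scale_scale),
    mu_alpha = stats::rnorm(1, 0, loc_scale),
    tau_alpha = half(1, scale_scale),
    psi = min(max(stats::rbeta(1, psi_prior[1], psi_prior[2]), 1e-3),
              1 - 1e-3),
    theta = stats::rgamma(1, theta_prior[1], theta_prior[2]) + 1e-3)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate a two-period multi-scale landscape
#'
#' Simulates compositional land-cover proportions at nested buffer radii for
#' every site and both periods, mimicking how real buffer covariates arise:
#' the composition within a larger buffer is the area-weighted average of the
#' next smaller buffer and the fresh annulus between them. Each site's
#' composition at the smallest radius is a Dirichlet draw; each annulus mixes
#' a fresh Dirichlet draw (the surrounding neighbourhood) in with weight
#' `area_fraction / spatial_smoothness`, so consecutive radii are strongly
#' autocorrelated while distant radii decorrelate — larger
#' `spatial_smoothness` slows the decay (in the limit all radii at a site are
#' identical). Period 2 equals Period 1 perturbed by a site x type
#' logistic-normal shock of standard deviation `shock_sd`, shared across
#' radii so temporal change is coherent across scales.
#'
#' @param design a [survey_design()].
#' @param grid a [build_scale_grid()].
#' @param seed integer seed.
#' @param spatial_smoothness positive; divides the annulus area fraction in
#'   the radius-to-radius mixing weight. 1 = geometric (area-true) mixing.
#' @param shock_sd standard deviation of the between-period log-ratio shock;
#'   0 makes the periods identical.
#' @param dirichlet_alpha Dirichlet concentration for the site and annulus
#'   compositions (scalar or length-M).
#' @return a [landcover_stack()].
#' @export
generate_landscape <- function(design, grid, seed = 1,
                               spatial_smoothness = 1, shock_sd = 0.3,
                               dirichlet_alpha = 2) {
  stopifnot(inherits(design, "survey_design"), inherits(grid, "scale_grid"))
  if (spatial_smoothness <= 0) stop("spatial_smoothness must be > 0",
                                    call. = FALSE)
  if (shock_sd < 0) stop("shock_sd must be >= 0", call. = FALSE)
  set.seed(split_seed(seed, 11L))
  J <- design$n_sites; M <- design$n_landcover
  C <- length(grid$radii)
  alpha <- rep(dirichlet_alpha, length.out = M)
  arr <- array(NA_real_, c(J, M, C, 2L))
  arr[, , 1, 1] <- rdirichlet(J, alpha)             # innermost buffer
  for (cc in seq_len(C)[-1]) {
    u <- (1 - (grid$radii[cc - 1] / grid$radii[cc])^2) / spatial_smoothness
    u <- min(u, 1)
    arr[, , cc, 1] <- (1 - u) * arr[, , cc - 1, 1] + u * rdirichlet(J, alpha)
  }
  shock <- matrix(stats::rnorm(J * M, sd = shock_sd), J, M)
  for (cc in seq_len(C)) {
    z <- log(pmax(arr[, , cc, 1], 1e-12)) + shock
    ez <- exp(z - apply(z, 1, max))
    arr[, , cc, 2] <- ez / rowSums(ez)
  }
  if (shock_sd == 0) arr[, , , 2] <- arr[, , , 1]
  landcover_stack(arr, design, grid, tol = 1e-9)
}

#' Draw a true community from its hyperpriors
#'
#' Draws species-level parameters from the community hyperpriors:
#' `beta[i, m] ~ Normal(mu[m], tau[m])`, `alpha[i] ~ Normal(mu_alpha,
#' tau_alpha)`, `phi[i] ~ Normal(rho, sigma)`, and detection
#' `P[i] ~ Beta(psi * theta, (1 - psi) * theta)`. Each species x type pair is
#' assigned a generating scale of effect, drawn uniformly from the grid's
#' radii unless `true_scale` fixes one radius for all pairs.
#'
#' @param design a [survey_design()].
#' @param grid a [build_scale_grid()].
#' @param hyperparams a [community_hyperparams()].
#' @param seed integer seed.
#' @param true_scale `NULL` (uniform over the grid) or a single radius from
#'   the grid applied to every species x type.
#' @return a list of class `community_params` with elements `beta` (S x M),
#'   `alpha`, `phi`, `detect_p` (length S), `true_scale` (S x M), and the
#'   hyperparams used.
#' @export
generate_community <- function(design, grid, hyperparams = NULL, seed = 1,
                               true_scale = NULL) {
  stopifnot(inherits(design, "survey_design"), inherits(grid, "scale_grid"))
  hp <- hyperparams %||% community_hyperparams(design$n_landcover)
  stopifnot(inherits(hp, "community_hyperparams"),
            hp$n_landcover == design$n_landcover)
  set.seed(split_seed(seed, 12L))
  S <- design$n_species; M <- design$n_landcover
  beta <- matrix(stats::rnorm(S * M, mean = rep(hp$mu, each = S),
                              sd = rep(hp$tau, each = S)), S, M,
                 dimnames = list(design$species, design$types))
  alpha <- stats::rnorm(S, hp$mu_alpha, hp$tau_alpha)
  phi <- stats::rnorm(S, hp$rho, hp$sigma)
  a <- hp$psi * hp$theta; b <- (1 - hp$psi) * hp$theta
  detect_p <- stats::rbeta(S, a, b)
  if (is.null(true_scale)) {
    ts <- matrix(sample(grid$radii, S * M, replace = TRUE), S, M)
  } else {
    if (!true_scale %in% grid$radii)
      stop("true_scale must be a radius of the grid", call. = FALSE)
    ts <- matrix(true_scale, S, M)
  }
  dimnames(ts) <- dimnames(beta)
  names(alpha) <- names(phi) <- names(detect_p) <- design$species
  structure(list(beta = beta, alpha = alpha, phi = phi, detect_p = detect_p,
                 true_scale = ts, hyperparams = hp, beta_ab = c(a = a, b = b)),
            class = "community_params")
}

#' Simulate detection-thinned counts
#'
#' Generates latent true abundances and observed counts under the N-mixture
#' structure: `N[i,j,t] ~ Poisson(lambda[i,j,t])` with
#' `log lambda[i,j,1] = alpha_i + sum_m beta[i,m] E[i,j,m,1]` and a drift term
#' `phi_i` added in Period 2; every within-period replicate is an independent
#' `Binomial(N[i,j,t], P_i)` thinning of the same latent N. Under the
#' `"fixed50"` variant the linear predictor uses land cover at the smallest
#' radius for all species and omits the intercept (the compositional
#' parametrization has none; supplying nonzero `alpha` is an error); under
#' `"multiscale"` each species x type covariate is taken at that pair's
#' generating scale and the intercept is included.
#'
#' @param params a [generate_community()] result.
#' @param stack a [landcover_stack()].
#' @param design a [survey_design()].
#' @param seed integer seed.
#' @param model_variant `"multiscale"` (default) or `"fixed50"`.
#' @return list with `counts` (a [count_data()]), `N` (S x J x 2 latent
#'   abundance array), and `lambda` (S x J x 2 expected abundance).
#' @export
simulate_counts <- function(params, stack, design, seed = 1,
                            model_variant = c("multiscale", "fixed50")) {
  model_variant <- match.arg(model_variant)
  stopifnot(inherits(params, "community_params"),
            inherits(stack, "landcover_stack"),
            inherits(design, "survey_design"))
  S <- design$n_species; J <- design$n_sites
  if (model_variant == "fixed50") {
    if (any(params$alpha != 0))
      stop("fixed50 variant has no intercept: alpha must be all zero",
           call. = FALSE)
    E0 <- stack_at_radius(stack, stack$grid$min_radius)   # J x M x 2
    loglam1 <- params$beta %*% t(E0[, , 1])
    loglam2 <- params$beta %*% t(E0[, , 2]) + params$phi
  } else {
    map <- data.frame(
      species = rep(design$species, times = design$n_landcover),
      type = rep(design$types, each = S),
      radius = as.vector(params$true_scale))
    E <- stack_at_map(stack, map)                         # S x J x M x 2
    loglam1 <- matrix(0, S, J); loglam2 <- matrix(0, S, J)
    for (m in seq_len(design$n_landcover)) {
      loglam1 <- loglam1 + params$beta[, m] * E[, , m, 1]
      loglam2 <- loglam2 + params$beta[, m] * E[, , m, 2]
    }
    loglam1 <- loglam1 + params$alpha
    loglam2 <- loglam2 + params$alpha + params$phi
  }
  lambda <- array(c(exp(loglam1), exp(loglam2)), c(S, J, 2L),
                  dimnames = list(design$species, design$sites,
                                  paste0("t", 1:2)))
  set.seed(split_seed(seed, 13L))
  N <- array(stats::rpois(S * J * 2, lambda), dim(lambda),
             dimnames = dimnames(lambda))
  kmax <- max(design$replicates_per_period)
  y <- array(NA_integer_, c(S, J, 2L, kmax))
  for (t in 1:2) for (k in seq_len(design$replicates_per_period[t]))
    y[, , t, k] <- stats::rbinom(S * J, N[, , t], params$detect_p)
  list(counts = count_data(y, design), N = N, lambda = lambda)
}

#' Scale map of the generating scales of effect
#'
#' Converts the generating species x type scales of a simulated community
#' into an `optimal_scale_map`, e.g. to fit the multiscale model at the true
#' scales in recovery experiments.
#'
#' @param params a [generate_community()] result.
#' @param design the matching [survey_design()].
#' @return an `optimal_scale_map` data frame.
#' @export
true_scale_map <- function(params, design) {
  stopifnot(inherits(params, "community_params"),
            inherits(design, "survey_design"))
  out <- expand.grid(species = design$species, type = design$types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$radius <- params$true_scale[cbind(match(out$species, design$species),
                                        match(out$type, design$types))]
  out$score <- NA_real_
  new_scale_map(out, "truth")
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [generate_landscape()],
#' [generate_community()] and [simulate_counts()] from one master seed.
#'
#' @inheritParams simulate_counts
#' @inheritParams generate_landscape
#' @inheritParams generate_community
#' @param hyperparams optional [community_hyperparams()].
#' @return list with `stack`, `params`, `counts`, `N`, `lambda`.
#' @export
simulate_dataset <- function(design, grid, seed = 1, hyperparams = NULL,
                             true_scale = NULL,
                             model_variant = c("multiscale", "fixed50"),
                             spatial_smoothness = 1, shock_sd = 0.3) {
  model_variant <- match.arg(model_variant)
  stack <- generate_landscape(design, grid, seed = seed,
                              spatial_smoothness = spatial_smoothness,
                              shock_sd = shock_sd)
  params <- generate_community(design, grid, hyperparams, seed = seed,
                               true_scale = true_scale)
  if (model_variant == "fixed50") params$alpha[] <- 0
  sim <- simulate_counts(params, stack, design, seed = seed,
                         model_variant = model_variant)
  c(list(stack = stack, params = params), sim)
}
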