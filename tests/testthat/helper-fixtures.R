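# Shared fixture builders; everything is generated in code.

tiny_design <- function(n_sites = 6, n_species = 2, n_landcover = 3, ...)
  survey_design(n_sites, n_species, n_landcover, ...)

tiny_grid <- function() build_scale_grid(50, 150, 50)

# a minimal valid landcover stack with hand-set compositions
toy_stack <- function(design = tiny_design(), grid = tiny_grid(), seed = 1) {
  set.seed(seed)
  J <- design$n_sites; M <- design$n_landcover; C <- length(grid$radii)
  g <- array(rgamma(J * M * C * 2, shape = 2), c(J, M, C, 2))
  s <- apply(g, c(1, 3, 4), sum)
  for (m in seq_len(M)) g[, m, , ] <- g[, m, , ] / s
  landcover_stack(g, design, grid)
}

# counts array with the right NA structure from a dense S x J x 2 x kmax spec
toy_counts <- function(values, design = tiny_design()) {
  kmax <- max(design$replicates_per_period)
  arr <- array(NA_integer_,
               c(design$n_species, design$n_sites, 2L, kmax))
  for (t in 1:2)
    arr[, , t, seq_len(design$replicates_per_period[t])] <- values
  count_data(arr, design)
}

# independent brute-force oracle for the site marginal likelihood:
# plain natural-scale summation over the latent abundance
brute_marginal_loglik <- function(y, lambda, p, nmax) {
  N <- max(y):nmax
  tot <- 0
  for (n in N) tot <- tot + dpois(n, lambda) * prod(dbinom(y, n, p))
  log(tot)
}

# fake minimal abundance_fit for direct counterfactual unit tests
fake_fit <- function(beta, alpha, phi, E2, E1 = E2, P = NULL, N = NULL,
                     variant = "multiscale", cri_level = 0.89) {
  D <- dim(beta)[1]; S <- dim(beta)[2]
  design <- survey_design(n_sites = dim(E2)[2], n_species = S,
                          n_landcover = dim(beta)[3])
  structure(list(variant = variant,
                 draws = list(beta = beta, alpha = alpha, phi = phi,
                              P = P, N = N),
                 E1 = E1, E2 = E2, design = design, n_draws = D,
                 cri_level = cri_level, scale_map = NULL),
            class = "abundance_fit")
}

quick_spec <- function(variant = "fixed50", chains = 2, warmup = 400,
                       sampling = 300, adapt = 200)
  model_spec(variant, chains = chains, warmup = warmup, sampling = sampling,
             adapt = adapt)
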