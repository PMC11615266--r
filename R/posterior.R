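#' Posterior communities of true abundance
#'
#' Sums the posterior draws of latent true abundance over sites, giving
#' per-draw species totals and the community total for each period —
#' simulated posterior communities corrected for imperfect detection.
#'
#' @param fit an [fit_abundance_model()] result.
#' @return object of class `posterior_community`: `species_totals`
#'   (draw x species x period), `community_totals` (draw x period), and
#'   `summary`, a data frame of medians and equal-tailed credible intervals
#'   at the fit's configured level.
#' @export
posterior_true_abundance <- function(fit) {
  stopifnot(inherits(fit, "abundance_fit"))
  sp_tot <- apply(fit$draws$N, c(1, 2, 4), sum)
  dimnames(sp_tot) <- list(NULL, fit$design$species, paste0("t", 1:2))
  comm <- apply(sp_tot, c(1, 3), sum)
  lv <- fit$cri_level
  rows <- expand.grid(species = c(fit$design$species, "__community__"),
                      period = 1:2, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  qs <- t(apply(rows, 1, function(r) {
    x <- if (r[["species"]] == "__community__")
      comm[, as.integer(r[["period"]])]
    else sp_tot[, r[["species"]], as.integer(r[["period"]])]
    cri(x, lv)
  }))
  summary <- cbind(rows, as.data.frame(qs))
  structure(list(species_totals = sp_tot, community_totals = comm,
                 summary = summary, cri_level = lv),
            class = "posterior_community")
}

#' @export
print.posterior_community <- function(x, ...) {
  cm <- x$summary[x$summary$species == "__community__", ]
  cat(sprintf(
    "posterior_community: totals t1 %.0f [%.0f, %.0f], t2 %.0f [%.0f, %.0f] (%.0f%% CrI)\n",
    cm$median[1], cm$lower[1], cm$upper[1],
    cm$median[2], cm$lower[2], cm$upper[2], 100 * x$cri_level))
  invisible(x)
}

#' Posterior retrodiction check
#'
#' Posterior-predictive comparison of total detections: for each draw,
#' simulates replicate counts from the fitted detection model applied to that
#' draw's latent abundances, totals them per species and period, and compares
#' against the observed totals.
#'
#' @param fit an [fit_abundance_model()] result.
#' @param seed integer seed for the predictive simulation.
#' @return data frame with one row per species x period: observed total,
#'   posterior-predictive median and credible interval, and whether the
#'   observation falls inside the interval.
#' @export
retrodiction_check <- function(fit, seed = 1) {
  stopifnot(inherits(fit, "abundance_fit"))
  set.seed(split_seed(seed, 21L))
  design <- fit$design
  S <- design$n_species; J <- design$n_sites
  D <- fit$n_draws
  K <- design$replicates_per_period
  lv <- fit$cri_level
  out <- expand.grid(species = design$species, period = 1:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$observed <- NA_real_
  out$median <- out$lower <- out$upper <- NA_real_
  for (t in 1:2) {
    yobs <- apply(fit$counts$counts[, , t, seq_len(K[t]), drop = FALSE],
                  1, sum)
    Nt <- fit$draws$N[, , , t, drop = FALSE]; dim(Nt) <- c(D, S, J)
    tot <- matrix(0, D, S)
    for (k in seq_len(K[t])) {
      sim <- array(stats::rbinom(D * S * J, as.vector(Nt),
                                 rep(as.vector(fit$draws$P), J)),
                   c(D, S, J))
      tot <- tot + apply(sim, c(1, 2), sum)
    }
    for (i in seq_len(S)) {
      r <- out$species == design$species[i] & out$period == t
      q <- cri(tot[, i], lv)
      out$observed[r] <- yobs[i]
      out$median[r] <- q[1]; out$lower[r] <- q[2]; out$upper[r] <- q[3]
    }
  }
  out$inside <- out$observed >= out$lower & out$observed <= out$upper
  out
}
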