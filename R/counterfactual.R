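#' Land-cover-only counterfactual Period-2 abundance
#'
#' For every posterior draw, computes the expected Period-2 abundance of each
#' species had abundance only been able to change through land-cover change:
#' the drift term is set to zero and the draw's habitat effects (and
#' intercepts, for the multiscale variant) are applied to the Period-2 land
#' cover. By default a fresh Poisson realization is drawn per species, site
#' and draw, matching the stochastic width of the full model's posterior
#' communities; `stochastic = FALSE` returns the Poisson means instead.
#'
#' @param fit an [fit_abundance_model()] result.
#' @param stochastic draw Poisson realizations (default) or sum expectations.
#' @param seed integer seed for the Poisson draws.
#' @return list with `species_totals` (draw x species) and
#'   `community_totals` (per draw).
#' @export
expected_N_phi0 <- function(fit, stochastic = TRUE, seed = 1) {
  stopifnot(inherits(fit, "abundance_fit"))
  design <- fit$design
  S <- design$n_species; J <- design$n_sites; M <- design$n_landcover
  D <- fit$n_draws
  set.seed(split_seed(seed, 31L))
  totals <- matrix(0, D, S, dimnames = list(NULL, design$species))
  multiscale <- fit$variant == "multiscale"
  for (d in seq_len(D)) {
    beta_d <- fit$draws$beta[d, , , drop = FALSE]; dim(beta_d) <- c(S, M)
    loglam <- matrix(0, S, J)
    if (multiscale) {
      for (m in seq_len(M)) {
        E2m <- fit$E2[, , m, drop = FALSE]; dim(E2m) <- c(S, J)
        loglam <- loglam + beta_d[, m] * E2m
      }
      loglam <- loglam + fit$draws$alpha[d, ]
    } else {
      loglam <- beta_d %*% t(fit$E2)      # E2 is J x M
    }
    lam <- exp(loglam)
    totals[d, ] <- if (stochastic)
      rowSums(matrix(stats::rpois(S * J, lam), S, J))
    else rowSums(lam)
  }
  list(species_totals = totals, community_totals = rowSums(totals))
}

#' Per-draw percent change in abundance
#'
#' `100 * (n2 - n1) / n1` per aligned posterior draw, with Period-1 zeros
#' replaced by 1e-10 before dividing (so a species absent in Period 1 but
#' present in Period 2 shows an enormous positive change rather than a
#' division by zero).
#'
#' @param n1,n2 aligned vectors of per-draw totals for the two periods.
#' @return numeric vector of per-draw percent changes.
#' @export
percent_change <- function(n1, n2) {
  stopifnot(length(n1) == length(n2))
  denom <- ifelse(n1 == 0, 1e-10, n1)
  100 * (n2 - n1) / denom
}

#' Classify a species trend pair for space-for-time validity
#'
#' Compares the credible interval of the true (full-model) percent change
#' against the land-cover-only counterfactual percent change. A trend is
#' significant when its interval excludes zero. Categories:
#' `opposite_significant` (both significant, opposite signs),
#' `one_sided_mismatch` (exactly one significant), `both_nonsignificant`,
#' `same_direction_significant` (both significant, same sign, disjoint
#' intervals), `same_direction_overlapping` (both significant, same sign,
#' overlapping intervals).
#'
#' @param true_lower,true_upper credible bounds of the true change
#'   (vectorized).
#' @param cf_lower,cf_upper credible bounds of the counterfactual change.
#' @return factor of categories.
#' @export
classify_species <- function(true_lower, true_upper, cf_lower, cf_upper) {
  stopifnot(all(true_lower <= true_upper), all(cf_lower <= cf_upper))
  levels <- c("opposite_significant", "one_sided_mismatch",
              "both_nonsignificant", "same_direction_significant",
              "same_direction_overlapping")
  sig_t <- true_lower > 0 | true_upper < 0
  sig_c <- cf_lower > 0 | cf_upper < 0
  sign_t <- ifelse(true_lower > 0, 1, -1)
  sign_c <- ifelse(cf_lower > 0, 1, -1)
  overlap <- pmax(true_lower, cf_lower) <= pmin(true_upper, cf_upper)
  out <- ifelse(!sig_t & !sig_c, "both_nonsignificant",
         ifelse(xor(sig_t, sig_c), "one_sided_mismatch",
         ifelse(sign_t != sign_c, "opposite_significant",
         ifelse(overlap, "same_direction_overlapping",
                "same_direction_significant"))))
  factor(out, levels = levels)
}

#' Species and community trend summary with the counterfactual
#'
#' Builds the space-for-time test table from a fitted model: per-draw true
#' percent change (Period-1 vs Period-2 posterior species totals) and
#' counterfactual percent change (Period-1 totals vs the land-cover-only
#' Period-2 totals from [expected_N_phi0()]), summarized per species by
#' median and credible interval and classified by [classify_species()].
#'
#' @param fit an [fit_abundance_model()] result.
#' @param seed integer seed for the counterfactual Poisson draws.
#' @param stochastic passed to [expected_N_phi0()].
#' @return data frame of class `trend_summary`, one row per species, with
#'   attribute `community`: the community-total true and counterfactual
#'   percent changes (median and CrI).
#' @export
sft_trends <- function(fit, seed = 1, stochastic = TRUE) {
  stopifnot(inherits(fit, "abundance_fit"))
  post <- posterior_true_abundance(fit)
  cf <- expected_N_phi0(fit, stochastic = stochastic, seed = seed)
  lv <- fit$cri_level
  S <- fit$design$n_species
  out <- data.frame(species = fit$design$species,
                    true_median = NA_real_, true_lower = NA_real_,
                    true_upper = NA_real_, cf_median = NA_real_,
                    cf_lower = NA_real_, cf_upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(S)) {
    n1 <- post$species_totals[, i, 1]
    tq <- cri(percent_change(n1, post$species_totals[, i, 2]), lv)
    cq <- cri(percent_change(n1, cf$species_totals[, i]), lv)
    out[i, 2:4] <- tq; out[i, 5:7] <- cq
  }
  out$category <- classify_species(out$true_lower, out$true_upper,
                                   out$cf_lower, out$cf_upper)
  comm1 <- post$community_totals[, 1]
  community <- rbind(
    true = cri(percent_change(comm1, post$community_totals[, 2]), lv),
    counterfactual = cri(percent_change(comm1, cf$community_totals), lv))
  attr(out, "community") <- community
  attr(out, "cri_level") <- lv
  class(out) <- c("trend_summary", "data.frame")
  out
}

#' Space-for-time validity report
#'
#' Tabulates the five-way classification shares, the community-total percent
#' change (true and counterfactual), and optionally appends an external
#' per-species reference trend column for side-by-side comparison (the
#' external series is passed through, never modelled).
#'
#' @param trends a [sft_trends()] result.
#' @param external optional data frame with columns `species` and `change`
#'   (reference percent changes).
#' @return list with `trends` (per-species table, possibly with
#'   `external_change`), `shares` (category counts and percent shares), and
#'   `community` (percent-change summary matrix).
#' @export
sft_validity_report <- function(trends, external = NULL) {
  stopifnot(inherits(trends, "trend_summary"))
  tab <- table(trends$category)
  shares <- data.frame(category = names(tab), n = as.integer(tab),
                       share = 100 * as.integer(tab) / nrow(trends))
  out_tr <- as.data.frame(trends)
  if (!is.null(external)) {
    stopifnot(all(c("species", "change") %in% names(external)))
    out_tr$external_change <-
      external$change[match(out_tr$species, external$species)]
  }
  list(trends = out_tr, shares = shares,
       community = attr(trends, "community"))
}
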