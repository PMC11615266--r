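#' Collapse Period-2 replicates to the within-period maximum
#'
#' For scale selection the response is a single number per species, site and
#' period: the Period-1 count as-is, and in Period 2 the maximum raw count
#' over the back-to-back replicates, since the temporal maximum better
#' represents the number of birds associated with the surrounding land cover.
#'
#' @param counts a [count_data()].
#' @return integer array species x sites x periods.
#' @export
collapse_period2_max <- function(counts) {
  stopifnot(inherits(counts, "count_data"))
  apply(counts$counts, c(1, 2, 3), max, na.rm = TRUE)
}

#' Fit a univariate Poisson scale-selection model
#'
#' `y ~ Poisson(exp(zeta + eta * E))` for one species, land-cover type,
#' radius, and period, fit by maximum likelihood through [stats::glm()]. An
#' all-zero response has no finite intercept MLE and is flagged degenerate
#' instead of fit.
#'
#' @param y non-negative integer response vector.
#' @param E covariate vector (land-cover proportion), same length.
#' @return list with `zeta`, `eta`, `converged`, `degenerate`.
#' @export
fit_univariate <- function(y, E) {
  stopifnot(length(y) == length(E), all(y >= 0))
  if (all(y == 0))
    return(list(zeta = -Inf, eta = 0, converged = FALSE, degenerate = TRUE))
  if (length(unique(E)) < 2L) {
    # constant covariate: slope unidentified; intercept-only MLE
    return(list(zeta = log(mean(y)), eta = 0, converged = TRUE,
                degenerate = TRUE))
  }
  fit <- suppressWarnings(stats::glm(y ~ E, family = stats::poisson()))
  list(zeta = unname(stats::coef(fit)[1]), eta = unname(stats::coef(fit)[2]),
       converged = fit$converged, degenerate = FALSE)
}

#' Leave-one-out predictions from a univariate Poisson model
#'
#' For each observation, refits the univariate Poisson log-link model on the
#' remaining observations and predicts the held-out response. The refits are
#' exact maximum-likelihood solutions, obtained by a Newton iteration run
#' jointly across all folds (warm-started at the full-data fit); a fold whose
#' refit is degenerate (all-zero training response, constant training
#' covariate, or no convergence) yields `NA` and is excluded pairwise from
#' downstream correlations.
#'
#' @param y non-negative integer response vector (length >= 3).
#' @param E covariate vector.
#' @param max_iter,tol Newton iteration controls.
#' @return numeric vector of held-out predictions, `NA` where flagged.
#' @export
loo_predictions <- function(y, E, max_iter = 100L, tol = 1e-9) {
  n <- length(y)
  if (n < 3L) stop("leave-one-out needs at least 3 observations",
                   call. = FALSE)
  stopifnot(length(E) == n, all(y >= 0))
  pred <- rep(NA_real_, n)
  full <- fit_univariate(y, E)
  z0 <- if (is.finite(full$zeta)) full$zeta else log(mean(y) + 0.5)
  e0 <- full$eta
  z <- rep(z0, n); e <- rep(e0, n)
  sy <- sum(y); syE <- sum(y * E)
  ok <- rep(TRUE, n)
  # folds whose training response is all zero are degenerate
  ok[sy - y == 0] <- FALSE
  # folds whose training covariate is constant are unidentified
  for (f in which(ok)) if (length(unique(E[-f])) < 2L) ok[f] <- FALSE
  active <- which(ok)
  done <- logical(n)
  for (it in seq_len(max_iter)) {
    if (length(active) == 0L) break
    za <- z[active]; ea <- e[active]
    Mu <- exp(outer(za, rep(1, n)) + outer(ea, E))       # fold x obs
    mu_ff <- Mu[cbind(seq_along(active), active)]
    s0 <- rowSums(Mu) - mu_ff
    s1 <- as.vector(Mu %*% E) - mu_ff * E[active]
    s2 <- as.vector(Mu %*% (E^2)) - mu_ff * E[active]^2
    g1 <- (sy - y[active]) - s0
    g2 <- (syE - y[active] * E[active]) - s1
    det <- s0 * s2 - s1^2
    bad <- !is.finite(det) | det <= 1e-300
    dz <- (s2 * g1 - s1 * g2) / det
    de <- (s0 * g2 - s1 * g1) / det
    dz <- pmax(pmin(dz, 2), -2); de <- pmax(pmin(de, 2), -2)
    z[active] <- pmax(pmin(za + dz, 50), -50)
    e[active] <- pmax(pmin(ea + de, 50), -50)
    conv <- abs(g1) < tol * (1 + abs(sy)) & abs(g2) < tol * (1 + abs(syE))
    done[active[conv & !bad]] <- TRUE
    ok[active[bad]] <- FALSE
    active <- active[!conv & !bad]
  }
  ok[!done] <- FALSE
  idx <- which(ok)
  pred[idx] <- exp(z[idx] + e[idx] * E[idx])
  pred
}

#' Enumerate the scale-selection model grid
#'
#' One univariate model exists per species x land-cover type x radius; this
#' returns the bookkeeping of that enumeration without fitting anything.
#'
#' @param design a [survey_design()].
#' @param grid a [build_scale_grid()].
#' @return list with `n_models` (= S x M x C), `n_map_entries` (= S x M), and
#'   `configurations`, a data frame with one row per model.
#' @export
scale_selection_plan <- function(design, grid) {
  stopifnot(inherits(design, "survey_design"), inherits(grid, "scale_grid"))
  conf <- expand.grid(species = design$species, type = design$types,
                      radius = grid$radii, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  list(n_models = nrow(conf),
       n_map_entries = design$n_species * design$n_landcover,
       configurations = conf)
}

new_scale_map <- function(df, method) {
  df$method <- method
  rownames(df) <- NULL
  class(df) <- c("optimal_scale_map", "data.frame")
  df
}

#' Select optimal scales by leave-one-out predictive correlation
#'
#' For every species and land-cover type, fits period-specific univariate
#' Poisson models at each candidate radius, computes leave-one-out
#' out-of-sample predictions, and scores each radius by the correlation
#' (Pearson or Spearman) between the pooled observed responses of both
#' periods and their pooled LOO predictions. The radius maximizing the
#' correlation wins; ties go to the smallest radius (the most local scale),
#' and radii with undefined correlations (zero-variance predictions, too few
#' valid folds) never win.
#'
#' @param counts a [count_data()].
#' @param stack a [landcover_stack()].
#' @param method `"pearson"` or `"spearman"`.
#' @return an `optimal_scale_map` data frame (columns species, type, radius,
#'   score, method) with attributes `n_models` (models enumerated) and
#'   `scores` (species x type x radius array of all correlations).
#' @export
select_scale_correlation <- function(counts, stack,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "count_data"),
            inherits(stack, "landcover_stack"))
  design <- counts$design
  grid <- stack$grid
  resp <- collapse_period2_max(counts)
  S <- design$n_species; M <- design$n_landcover; C <- length(grid$radii)
  scores <- array(NA_real_, c(S, M, C),
                  dimnames = list(design$species, design$types,
                                  as.character(grid$radii)))
  n_models <- 0L
  for (i in seq_len(S)) for (m in seq_len(M)) {
    y1 <- resp[i, , 1]; y2 <- resp[i, , 2]
    obs <- c(y1, y2)
    for (cc in seq_len(C)) {
      n_models <- n_models + 1L
      pr <- c(loo_predictions(y1, stack$proportions[, m, cc, 1]),
              loo_predictions(y2, stack$proportions[, m, cc, 2]))
      keep <- !is.na(pr)
      if (sum(keep) < 3L) next
      if (stats::sd(pr[keep]) == 0 || stats::sd(obs[keep]) == 0) next
      scores[i, m, cc] <- stats::cor(obs[keep], pr[keep], method = method)
    }
  }
  out <- expand.grid(species = design$species, type = design$types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$radius <- NA_real_; out$score <- NA_real_
  for (r in seq_len(nrow(out))) {
    i <- match(out$species[r], design$species)
    m <- match(out$type[r], design$types)
    s <- scores[i, m, ]
    s[is.na(s)] <- -Inf                   # undefined never wins
    best <- which.max(s)                  # first max = smallest radius on tie
    out$radius[r] <- grid$radii[best]
    out$score[r] <- if (is.finite(s[best])) s[best] else NA_real_
  }
  map <- new_scale_map(out, method)
  attr(map, "n_models") <- n_models
  attr(map, "scores") <- scores
  map
}

#' Fixed smallest-radius scale map
#'
#' The local-only baseline: every species x type pair is assigned the grid's
#' smallest radius.
#'
#' @param design a [survey_design()].
#' @param grid a [build_scale_grid()].
#' @return an `optimal_scale_map` data frame.
#' @export
select_scale_fixed <- function(design, grid) {
  out <- expand.grid(species = design$species, type = design$types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$radius <- grid$min_radius
  out$score <- NA_real_
  new_scale_map(out, "fixed50")
}
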