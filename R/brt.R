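#' Boosted-regression-tree settings
#'
#' Defaults are the tuned ensemble settings used for scale selection on the
#' full study: 20,000 depth-1 trees, shrinkage 1e-4, bag fraction 0.5, and a
#' minimum of 25 observations per terminal node. Test-scale analyses use far
#' fewer trees with a larger shrinkage.
#'
#' @param n_trees number of boosting rounds.
#' @param shrinkage learning rate.
#' @param interaction_depth maximum tree depth (1 = stumps).
#' @param bag_fraction row subsampling fraction per round.
#' @param min_node minimum observations in a terminal node.
#' @return a list of class `brt_settings`.
#' @export
brt_settings <- function(n_trees = 20000L, shrinkage = 1e-4,
                         interaction_depth = 1L, bag_fraction = 0.5,
                         min_node = 25L) {
  stopifnot(n_trees >= 1, shrinkage > 0, interaction_depth >= 1,
            bag_fraction > 0, bag_fraction <= 1, min_node >= 1)
  structure(list(n_trees = as.integer(n_trees), shrinkage = shrinkage,
                 interaction_depth = as.integer(interaction_depth),
                 bag_fraction = bag_fraction, min_node = as.integer(min_node)),
            class = "brt_settings")
}

#' Select optimal scales by boosted-regression-tree relative influence
#'
#' Fits one gradient-boosted tree ensemble per species (Poisson loss, via
#' xgboost) on the full predictor matrix of all land-cover types at all radii
#' (M x C columns), with the collapsed responses of both periods stacked.
#' Relative influence of each predictor is its normalized split gain summed
#' over the ensemble; for each land-cover type, the radius with the highest
#' relative influence wins (ties to the smallest radius).
#'
#' Species with too few nonzero responses to support an ensemble inherit the
#' map of the fit species whose site x period count profile is most similar
#' (highest Spearman correlation); an explicit `donor_map` (named character
#' vector, species -> donor species) takes precedence over that rule.
#'
#' @param counts a [count_data()].
#' @param stack a [landcover_stack()].
#' @param settings a [brt_settings()].
#' @param seed integer seed for the stochastic bagging.
#' @param min_nonzero species with fewer nonzero (site, period) responses
#'   than this fall back to a donor species.
#' @param donor_map optional named character vector of explicit donors.
#' @return an `optimal_scale_map` data frame with columns species, type,
#'   radius, score (relative influence, per cent), method, donor (NA unless
#'   the fallback was used), plus attribute `influence` (species x type x
#'   radius array).
#' @export
select_scale_brt <- function(counts, stack, settings = brt_settings(),
                             seed = 1, min_nonzero = 5L, donor_map = NULL) {
  stopifnot(inherits(counts, "count_data"),
            inherits(stack, "landcover_stack"),
            inherits(settings, "brt_settings"))
  design <- counts$design
  grid <- stack$grid
  resp <- collapse_period2_max(counts)
  S <- design$n_species; M <- design$n_landcover; C <- length(grid$radii)
  J <- design$n_sites
  feat <- as.vector(outer(design$types, grid$radii, paste, sep = "_r"))
  # rows: J sites of period 1 then J sites of period 2; cols: M*C proportions
  X <- rbind(matrix(aperm(stack$proportions[, , , 1, drop = FALSE],
                          c(1, 2, 3, 4)), J, M * C),
             matrix(aperm(stack$proportions[, , , 2, drop = FALSE],
                          c(1, 2, 3, 4)), J, M * C))
  colnames(X) <- feat
  infl <- array(NA_real_, c(S, M, C),
                dimnames = list(design$species, design$types,
                                as.character(grid$radii)))
  fit_ok <- logical(S)
  for (i in seq_len(S)) {
    y <- c(resp[i, , 1], resp[i, , 2])
    if (sum(y > 0) < min_nonzero) next
    bst <- xgboost::xgb.train(
      params = list(objective = "count:poisson", eta = settings$shrinkage,
                    max_depth = settings$interaction_depth,
                    subsample = settings$bag_fraction,
                    min_child_weight = settings$min_node,
                    nthread = 1, seed = split_seed(seed, 100L + i)),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = settings$n_trees, verbose = 0)
    imp <- xgboost::xgb.importance(model = bst)
    v <- stats::setNames(rep(0, length(feat)), feat)
    if (!is.null(imp) && nrow(imp) > 0) v[imp$Feature] <- imp$Gain
    infl[i, , ] <- matrix(100 * v / max(sum(v), .Machine$double.eps), M, C)
    fit_ok[i] <- sum(v) > 0
  }
  out <- expand.grid(species = design$species, type = design$types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$radius <- NA_real_; out$score <- NA_real_
  out$donor <- NA_character_
  profiles <- sapply(seq_len(S), function(i) c(resp[i, , 1], resp[i, , 2]))
  for (i in seq_len(S)) {
    donor <- i
    if (!fit_ok[i]) {
      if (!is.null(donor_map) && design$species[i] %in% names(donor_map)) {
        donor <- match(donor_map[[design$species[i]]], design$species)
        if (is.na(donor)) stop("unknown donor species for ",
                               design$species[i], call. = FALSE)
      } else {
        cand <- which(fit_ok)
        if (length(cand) == 0L)
          stop("no species had enough data to fit an ensemble", call. = FALSE)
        sim <- sapply(cand, function(jj)
          suppressWarnings(stats::cor(profiles[, i], profiles[, jj],
                                      method = "spearman")))
        sim[is.na(sim)] <- -Inf
        donor <- cand[which.max(sim)]
      }
      if (!fit_ok[donor])
        stop("donor species '", design$species[donor],
             "' has no fitted ensemble", call. = FALSE)
    }
    for (m in seq_len(M)) {
      s <- infl[donor, m, ]
      best <- which.max(s)                # first max = smallest radius on tie
      r <- out$species == design$species[i] & out$type == design$types[m]
      out$radius[r] <- grid$radii[best]
      out$score[r] <- s[best]
      if (donor != i) out$donor[r] <- design$species[donor]
    }
  }
  map <- new_scale_map(out, "brt")
  attr(map, "influence") <- infl
  map
}
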