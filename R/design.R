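#' Survey design for a two-period point-count study
#'
#' Describes the dimensions of a replicated point-count survey: number of
#' sites, species, and land-cover types, the two sampling periods, and the
#' number of back-to-back within-period replicates per period. The default
#' mirrors a design with a single count in Period 1 and two back-to-back
#' replicate counts in Period 2 (the replication needed to estimate detection
#' probability).
#'
#' @param n_sites number of sampling locations (J).
#' @param n_species number of species (S).
#' @param n_landcover number of land-cover types (M).
#' @param replicates_per_period integer vector of length 2: within-period
#'   temporal replicates for Period 1 and Period 2.
#' @param species,sites,types optional character labels; defaults are
#'   generated (`sp01`, `site001`, `lc1`, ...).
#' @return an object of class `survey_design`.
#' @examples
#' survey_design(n_sites = 10, n_species = 4, n_landcover = 3)
#' @export
survey_design <- function(n_sites, n_species, n_landcover,
                          replicates_per_period = c(1L, 2L),
                          species = NULL, sites = NULL, types = NULL) {
  stopifnot(n_sites >= 1, n_species >= 1, n_landcover >= 1,
            length(replicates_per_period) == 2L,
            all(replicates_per_period >= 1))
  n_sites <- as.integer(n_sites)
  n_species <- as.integer(n_species)
  n_landcover <- as.integer(n_landcover)
  species <- species %||% sprintf("sp%02d", seq_len(n_species))
  sites <- sites %||% sprintf("site%03d", seq_len(n_sites))
  types <- types %||% sprintf("lc%d", seq_len(n_landcover))
  stopifnot(length(species) == n_species, !anyDuplicated(species),
            length(sites) == n_sites, !anyDuplicated(sites),
            length(types) == n_landcover, !anyDuplicated(types))
  structure(list(
    n_sites = n_sites, n_species = n_species, n_landcover = n_landcover,
    periods = c(1L, 2L),
    replicates_per_period = as.integer(replicates_per_period),
    species = as.character(species), sites = as.character(sites),
    types = as.character(types)
  ), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "survey_design: %d species x %d sites x %d land-cover types, 2 periods (replicates %d/%d)\n",
    x$n_species, x$n_sites, x$n_landcover,
    x$replicates_per_period[1], x$replicates_per_period[2]))
  invisible(x)
}

#' Build a grid of buffer radii (candidate scales of effect)
#'
#' Land cover is measured as proportions within nested circular buffers. The
#' default grid of 50 m to 1500 m in 50 m steps gives 30 candidate radii.
#'
#' @param min_radius smallest radius in metres.
#' @param max_radius largest radius in metres.
#' @param step grid step in metres; `(max_radius - min_radius)` must be an
#'   exact multiple of `step`.
#' @return an object of class `scale_grid` with element `radii`.
#' @examples
#' length(build_scale_grid()$radii)  # 30
#' @export
build_scale_grid <- function(min_radius = 50, max_radius = 1500, step = 50) {
  stopifnot(min_radius > 0, step > 0, min_radius <= max_radius)
  span <- max_radius - min_radius
  if (abs(span / step - round(span / step)) > 1e-9)
    stop("(max_radius - min_radius) must be divisible by step", call. = FALSE)
  radii <- seq(min_radius, max_radius, by = step)
  structure(list(min_radius = min_radius, max_radius = max_radius,
                 step = step, radii = radii),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("scale_grid: %d radii from %g to %g m (step %g m)\n",
              length(x$radii), x$min_radius, x$max_radius, x$step))
  invisible(x)
}
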