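#' Count data container
#'
#' Dense array of observed counts indexed species x site x period x replicate.
#' Cells for replicates the design does not allow (e.g. a second replicate in
#' Period 1) are `NA` structurally and must stay `NA`.
#'
#' @param counts integer array `[n_species, n_sites, 2, max_replicates]`, or a
#'   value recyclable to it.
#' @param design a [survey_design()].
#' @return object of class `count_data`.
#' @export
count_data <- function(counts, design) {
  stopifnot(inherits(design, "survey_design"))
  kmax <- max(design$replicates_per_period)
  dims <- c(design$n_species, design$n_sites, 2L, kmax)
  if (is.null(dim(counts))) counts <- array(counts, dims)
  stopifnot(identical(dim(counts), as.integer(dims)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(design$species, design$sites,
                           paste0("t", 1:2), paste0("k", seq_len(kmax)))
  for (t in 1:2) {
    kt <- design$replicates_per_period[t]
    if (kt < kmax && any(!is.na(counts[, , t, (kt + 1):kmax])))
      stop(sprintf("period %d allows only %d replicate(s)", t, kt),
           call. = FALSE)
    if (anyNA(counts[, , t, seq_len(kt)]))
      stop("missing counts inside the allowed replicate structure",
           call. = FALSE)
    if (kt < kmax) counts[, , t, (kt + 1):kmax] <- NA_integer_
  }
  obs <- counts[!is.na(counts)]
  if (any(obs < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, design = design), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  tot <- sum(x$counts, na.rm = TRUE)
  cat(sprintf("count_data: %d species x %d sites, 2 periods; %d birds counted\n",
              x$design$n_species, x$design$n_sites, tot))
  invisible(x)
}

#' @export
as.data.frame.count_data <- function(x, ...) {
  d <- x$design
  out <- expand.grid(species = d$species, site = d$sites,
                     period = 1:2, replicate = seq_len(dim(x$counts)[4]),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- as.vector(x$counts)
  out <- out[!is.na(out$count), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$species, out$site, out$period, out$replicate), ]
}

#' Land-cover stack container
#'
#' Compositional land-cover proportions indexed site x type x radius x period.
#' For every (site, radius, period) the proportions across types must sum to
#' one (closure), since the types partition the buffer area.
#'
#' @param proportions numeric array `[n_sites, n_landcover, n_radii, 2]`.
#' @param design a [survey_design()].
#' @param grid a [build_scale_grid()] object.
#' @param tol closure tolerance on the type sums.
#' @return object of class `landcover_stack`.
#' @export
landcover_stack <- function(proportions, design, grid, tol = 1e-6) {
  stopifnot(inherits(design, "survey_design"), inherits(grid, "scale_grid"))
  dims <- c(design$n_sites, design$n_landcover, length(grid$radii), 2L)
  stopifnot(identical(as.integer(dim(proportions)), as.integer(dims)))
  if (any(proportions < -tol) || any(proportions > 1 + tol))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  sums <- apply(proportions, c(1, 3, 4), sum)
  bad <- which(abs(sums - 1) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf(
      "land-cover proportions do not sum to 1 at site '%s', radius %g, period %d (sum = %.6f)",
      design$sites[b[1]], grid$radii[b[2]], b[3], sums[b[1], b[2], b[3]]),
      call. = FALSE)
  }
  dimnames(proportions) <- list(design$sites, design$types,
                                as.character(grid$radii), paste0("t", 1:2))
  structure(list(proportions = proportions, design = design, grid = grid),
            class = "landcover_stack")
}

#' @export
print.landcover_stack <- function(x, ...) {
  cat(sprintf("landcover_stack: %d sites x %d types x %d radii x 2 periods\n",
              dim(x$proportions)[1], dim(x$proportions)[2],
              dim(x$proportions)[3]))
  invisible(x)
}

#' @export
as.data.frame.landcover_stack <- function(x, ...) {
  d <- x$design
  out <- expand.grid(site = d$sites, type = d$types, radius = x$grid$radii,
                     period = 1:2, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$proportion <- as.vector(x$proportions)
  out[order(out$site, out$type, out$radius, out$period), ]
}

# E slice at one radius: sites x types x periods
stack_at_radius <- function(stack, radius) {
  idx <- match(radius, stack$grid$radii)
  if (is.na(idx)) stop(sprintf("radius %g not in grid", radius), call. = FALSE)
  stack$proportions[, , idx, , drop = FALSE][, , 1, ]
}

# E at per-(species, type) radii from a scale map: species x sites x types x periods
stack_at_map <- function(stack, map) {
  d <- stack$design
  E <- array(NA_real_, c(d$n_species, d$n_sites, d$n_landcover, 2L),
             dimnames = list(d$species, d$sites, d$types, paste0("t", 1:2)))
  for (i in seq_len(d$n_species)) for (m in seq_len(d$n_landcover)) {
    r <- map$radius[map$species == d$species[i] & map$type == d$types[m]]
    if (length(r) != 1L)
      stop(sprintf("scale map lacks a unique entry for (%s, %s)",
                   d$species[i], d$types[m]), call. = FALSE)
    c_idx <- match(r, stack$grid$radii)
    if (is.na(c_idx))
      stop(sprintf("mapped radius %g not in the stack's grid", r),
           call. = FALSE)
    E[i, , m, ] <- stack$proportions[, m, c_idx, ]
  }
  E
}
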