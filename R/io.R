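#' Read long-format count data
#'
#' Canonical exchange format: delimited text with columns
#' `species, site, period, replicate, count`. Species and site labels must
#' belong to the design. Because archived survey data often omit zero rows
#' (e.g. when only species seen more than once were retained), missing
#' (species, site, period, replicate) combinations are filled with zero when
#' `absence_is_zero = TRUE` (the default); with `absence_is_zero = FALSE` any
#' gap is an error.
#'
#' @param path file path (CSV; any delimiter `utils::read.csv` accepts via
#'   `sep`).
#' @param design a [survey_design()].
#' @param absence_is_zero fill omitted combinations with 0 instead of failing.
#' @param sep field separator.
#' @return a [count_data()] object.
#' @export
read_counts <- function(path, design, absence_is_zero = TRUE, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("species", "site", "period", "replicate", "count")
  if (!all(need %in% names(df)))
    stop("count file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad_sp <- setdiff(unique(df$species), design$species)
  if (length(bad_sp) > 0)
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  bad_site <- setdiff(unique(df$site), design$sites)
  if (length(bad_site) > 0)
    stop("unknown site label(s): ", paste(bad_site, collapse = ", "),
         call. = FALSE)
  if (any(!df$period %in% 1:2))
    stop("period must be 1 or 2", call. = FALSE)
  if (any(df$count < 0))
    stop("negative counts are invalid", call. = FALSE)
  if (any(df$count != round(df$count)))
    stop("counts must be integers", call. = FALSE)
  kall <- design$replicates_per_period[df$period]
  if (any(df$replicate < 1 | df$replicate > kall)) {
    r <- which(df$replicate < 1 | df$replicate > kall)[1]
    stop(sprintf("replicate %d not allowed in period %d under this design",
                 df$replicate[r], df$period[r]), call. = FALSE)
  }
  kmax <- max(design$replicates_per_period)
  arr <- array(NA_integer_, c(design$n_species, design$n_sites, 2L, kmax))
  for (t in 1:2)
    arr[, , t, seq_len(design$replicates_per_period[t])] <- 0L
  idx <- cbind(match(df$species, design$species),
               match(df$site, design$sites), df$period, df$replicate)
  if (anyDuplicated(idx))
    stop("duplicate rows for the same (species, site, period, replicate)",
         call. = FALSE)
  if (!absence_is_zero) {
    n_expected <- design$n_species * design$n_sites *
      sum(design$replicates_per_period)
    if (nrow(df) != n_expected)
      stop(sprintf("expected %d rows for a dense table, found %d (set absence_is_zero = TRUE to fill gaps)",
                   n_expected, nrow(df)), call. = FALSE)
  }
  arr[idx] <- as.integer(df$count)
  count_data(arr, design)
}

#' Write count data in the canonical long format
#'
#' @param x a [count_data()] object.
#' @param path output file path.
#' @export
write_counts <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-format land-cover proportions
#'
#' Columns `site, type, radius, period, proportion`. Every radius must belong
#' to the grid and every (site, radius, period) slice must be a complete
#' composition over the design's land-cover types summing to one.
#'
#' @param path file path.
#' @param design a [survey_design()].
#' @param grid a [build_scale_grid()] object.
#' @param tol closure tolerance.
#' @param sep field separator.
#' @return a [landcover_stack()] object.
#' @export
read_landcover <- function(path, design, grid, tol = 1e-6, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("site", "type", "radius", "period", "proportion")
  if (!all(need %in% names(df)))
    stop("land-cover file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad_site <- setdiff(unique(df$site), design$sites)
  if (length(bad_site) > 0)
    stop("unknown site label(s): ", paste(bad_site, collapse = ", "),
         call. = FALSE)
  bad_type <- setdiff(unique(df$type), design$types)
  if (length(bad_type) > 0)
    stop("unknown land-cover type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  bad_r <- setdiff(unique(df$radius), grid$radii)
  if (length(bad_r) > 0)
    stop("radius not in grid: ", paste(bad_r, collapse = ", "), call. = FALSE)
  arr <- array(NA_real_, c(design$n_sites, design$n_landcover,
                           length(grid$radii), 2L))
  idx <- cbind(match(df$site, design$sites), match(df$type, design$types),
               match(df$radius, grid$radii), df$period)
  if (anyDuplicated(idx))
    stop("duplicate (site, type, radius, period) rows", call. = FALSE)
  arr[idx] <- df$proportion
  if (anyNA(arr))
    stop("land-cover table is not dense over site x type x radius x period",
         call. = FALSE)
  landcover_stack(arr, design, grid, tol = tol)
}

#' Write a land-cover stack in the canonical long format
#' @param x a [landcover_stack()] object.
#' @param path output file path.
#' @export
write_landcover <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an optimal-scale map
#'
#' Delimited text with columns `species, type, radius, score, method`.
#'
#' @param path file path.
#' @param design optional [survey_design()]; if given, labels are validated
#'   and completeness (one row per species x type) enforced.
#' @return data frame of class `optimal_scale_map`.
#' @export
read_scale_map <- function(path, design = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "type", "radius")
  if (!all(need %in% names(df)))
    stop("scale map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$score)) df$score <- NA_real_
  if (is.null(df$method)) df$method <- NA_character_
  if (!is.null(design)) validate_scale_map(df, design)
  class(df) <- c("optimal_scale_map", "data.frame")
  df
}

#' @rdname read_scale_map
#' @param x an `optimal_scale_map` data frame.
#' @export
write_scale_map <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop rarely detected species
#'
#' Survey archives often retain only species seen more than once; applying
#' the same inclusion rule to both periods keeps the data comparable. Species
#' whose total detections across all sites, periods, and replicates fall
#' below `min_total` are removed (the abundance model itself never drops
#' species).
#'
#' @param counts a [count_data()].
#' @param min_total minimum total detections to keep a species (default 2,
#'   i.e. seen more than once).
#' @return a [count_data()] on the reduced design.
#' @export
filter_min_detections <- function(counts, min_total = 2L) {
  stopifnot(inherits(counts, "count_data"))
  tot <- apply(counts$counts, 1, sum, na.rm = TRUE)
  keep <- which(tot >= min_total)
  if (length(keep) == 0L) stop("no species meets the detection threshold",
                               call. = FALSE)
  d <- counts$design
  nd <- survey_design(d$n_sites, length(keep), d$n_landcover,
                      d$replicates_per_period,
                      species = d$species[keep], sites = d$sites,
                      types = d$types)
  count_data(counts$counts[keep, , , , drop = FALSE], nd)
}

validate_scale_map <- function(map, design) {
  full <- expand.grid(species = design$species, type = design$types,
                      stringsAsFactors = FALSE)
  key <- paste(map$species, map$type)
  if (anyDuplicated(key) || !setequal(key, paste(full$species, full$type)))
    stop("scale map must have exactly one row per species x land-cover type",
         call. = FALSE)
  invisible(map)
}
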