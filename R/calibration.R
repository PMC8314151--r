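#' Area-weighted surface distances between two observers' masks
#'
#' The raw material for tolerance calibration: for every surface point of
#' each mask, the pair (distance in mm to the other mask's surface, local
#' surface-element area in mm^2), pooled bidirectionally. Weighting
#' distances by element area removes the voxel-count bias of anisotropic
#' grids.
#'
#' @param a,b non-empty [binary_mask()] objects on the same grid.
#' @param table optional [build_neighborhood_table()].
#' @return a data.frame with columns `distance` (mm) and `area` (mm^2);
#'   rows are surface elements of both masks.
#' @export
pairwise_surface_distances <- function(a, b, table = NULL) {
  assert_comparable(a, b)
  if (foreground_count(a) == 0L || foreground_count(b) == 0L)
    stop("both masks must be non-empty for distance sampling", call. = FALSE)
  if (is.null(table)) table <- build_neighborhood_table(a$spacing)
  sa <- extract_surface(a, table)
  sb <- extract_surface(b, table)
  da <- distance_map(sa)
  db <- distance_map(sb)
  ia <- sa$grid > 0
  ib <- sb$grid > 0
  data.frame(distance = c(db$grid[ia], da$grid[ib]),
             area = c(sa$grid[ia], sb$grid[ib]))
}

# area-weighted percentile, step convention: smallest distance whose
# cumulative weight fraction reaches p/100 ("lower" at exact boundaries)
weighted_percentile <- function(distance, area, p) {
  ord <- order(distance)
  cw <- cumsum(area[ord]) / sum(area)
  distance[ord][which(cw >= p / 100 - 1e-12)[1]]
}

#' Calibrate organ-specific tolerances from inter-observer distances
#'
#' Maps pooled inter-observer surface-distance samples to one acceptable
#' tolerance tau (mm) per organ, as the area-weighted percentile (default
#' 95th) of the pooled bidirectional distance distribution across all
#' observer pairs and calibration scans. The intent is that deviations no
#' larger than typical expert disagreement go unpenalized.
#'
#' @param samples named list: organ name -> list of
#'   [pairwise_surface_distances()] data.frames (one per observer pair and
#'   scan). Every organ must have at least one sample.
#' @param percentile percentile of the pooled distribution, in (0, 100].
#' @return an object of class `tolerance_set`: list with `tolerances`
#'   (named numeric, mm) and `provenance` (percentile, per-organ sample
#'   counts).
#' @export
calibrate_tolerances <- function(samples, percentile = 95) {
  if (!is.list(samples) || is.null(names(samples)) ||
      any(!nzchar(names(samples))))
    stop("samples must be a named list keyed by organ", call. = FALSE)
  if (length(percentile) != 1L || is.na(percentile) ||
      percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]", call. = FALSE)
  taus <- vapply(names(samples), function(organ) {
    ss <- samples[[organ]]
    if (is.data.frame(ss)) ss <- list(ss)
    if (length(ss) == 0L)
      stop(sprintf("organ '%s' has no distance samples", organ),
           call. = FALSE)
    pooled <- do.call(rbind, ss)
    if (nrow(pooled) == 0L)
      stop(sprintf("organ '%s' has no distance samples", organ),
           call. = FALSE)
    weighted_percentile(pooled$distance, pooled$area, percentile)
  }, numeric(1))
  tolerance_set(taus,
                provenance = list(
                  percentile = percentile,
                  n_samples = vapply(samples, function(ss)
                    if (is.data.frame(ss)) 1L else length(ss), integer(1))))
}

#' Construct a tolerance set
#'
#' @param tolerances named numeric vector, organ name -> tau in mm (>= 0).
#' @param provenance optional list describing how the tolerances were
#'   obtained (e.g. percentile, sample counts).
#' @return an object of class `tolerance_set`.
#' @export
tolerance_set <- function(tolerances, provenance = list()) {
  if (is.null(names(tolerances)) || any(!nzchar(names(tolerances))))
    stop("tolerances must be named by organ", call. = FALSE)
  if (anyNA(tolerances) || any(tolerances < 0))
    stop("tolerances must be non-negative", call. = FALSE)
  structure(list(tolerances = tolerances, provenance = provenance),
            class = "tolerance_set")
}

#' @export
print.tolerance_set <- function(x, ...) {
  cat(sprintf("<tolerance_set> %d organs\n", length(x$tolerances)))
  for (o in names(x$tolerances))
    cat(sprintf("  %-22s %.3f mm\n", o, x$tolerances[[o]]))
  if (!is.null(x$provenance$percentile))
    cat(sprintf("  (area-weighted percentile %g)\n", x$provenance$percentile))
  invisible(x)
}

#' Write a tolerance set to JSON
#'
#' Serialized as `{"organ": tau_mm, ..., "_provenance": {...}}`.
#'
#' @param x a [tolerance_set()].
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_tolerances <- function(x, path) {
  stopifnot(inherits(x, "tolerance_set"))
  obj <- as.list(x$tolerances)
  obj[["_provenance"]] <- x$provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tolerance set from JSON
#'
#' @param path JSON file produced by [write_tolerances()] (or hand-written
#'   in the same organ -> mm layout).
#' @return a [tolerance_set()].
#' @export
read_tolerances <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- obj[["_provenance"]]
  obj[["_provenance"]] <- NULL
  taus <- unlist(obj)
  tolerance_set(taus, provenance = if (is.null(prov)) list() else prov)
}
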