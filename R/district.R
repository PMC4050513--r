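#' District geometry
#'
#' A rectangular study district in planar km with the locations of the two
#' large wood-panel (chipboard) industries and of the smaller wood factories.
#' Distance strata for residences follow the study design: within 2 km of a
#' chipboard industry; else within 4 km of a small wood factory; else at
#' least 4 km from any factory. Distances are Euclidean.
#'
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` in km.
#' @param chipboard two-column matrix of chipboard-industry coordinates.
#' @param small_factories two-column matrix of small wood-factory coordinates.
#' @return an object of class `district_spec`.
#' @export
district_spec <- function(extent = c(xmin = 0, xmax = 20, ymin = 0, ymax = 30),
                          chipboard = rbind(c(5, 4), c(14, 6)),
                          small_factories = rbind(
                            c(7, 8), c(10, 5), c(12, 10), c(8, 12),
                            c(16, 9), c(4, 9), c(11, 13), c(15, 12))) {
  extent <- unname(extent)
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  chipboard <- as.matrix(chipboard)
  small_factories <- as.matrix(small_factories)
  stopifnot(ncol(chipboard) == 2, nrow(chipboard) >= 1)
  pts <- rbind(chipboard, small_factories)
  inside <- pts[, 1] >= extent[1] & pts[, 1] <= extent[2] &
    pts[, 2] >= extent[3] & pts[, 2] <= extent[4]
  if (!all(inside)) stop("industry locations must lie inside the extent")
  structure(list(extent = c(xmin = extent[1], xmax = extent[2],
                            ymin = extent[3], ymax = extent[4]),
                 chipboard = chipboard, small_factories = small_factories),
            class = "district_spec")
}

# Minimum Euclidean distance from each point (n x 2) to a set of sources.
min_dist_to <- function(points, sources) {
  points <- as.matrix(points)
  if (is.null(sources) || nrow(sources) == 0)
    return(rep(Inf, nrow(points)))
  d <- outer(points[, 1], sources[, 1], "-")^2 +
    outer(points[, 2], sources[, 2], "-")^2
  sqrt(apply(d, 1, min))
}

#' Distance-stratum labels for residences
#'
#' Classify residences by their distance to the factories, with the
#' chipboard rule taking precedence: `"chipboard_lt2km"` if within 2 km of a
#' chipboard industry; otherwise `"small_factory_lt4km"` if within 4 km of a
#' small wood factory; otherwise `"ge4km"`. A residence 2-4 km from a
#' chipboard industry but at least 4 km from every small factory falls in
#' `"ge4km"` unless `chipboard_counts_as_small = TRUE`.
#'
#' @param points data frame or matrix with columns `x_km`, `y_km` (or two
#'   unnamed columns).
#' @param district a [district_spec()].
#' @param chipboard_counts_as_small should chipboard industries also count
#'   as small wood factories for the 4-km rule? Default `FALSE`.
#' @return factor with levels `chipboard_lt2km`, `small_factory_lt4km`,
#'   `ge4km`.
#' @export
distance_strata <- function(points, district, chipboard_counts_as_small = FALSE) {
  xy <- as_xy(points)
  d_chip <- min_dist_to(xy, district$chipboard)
  small <- district$small_factories
  if (chipboard_counts_as_small) small <- rbind(small, district$chipboard)
  d_small <- min_dist_to(xy, small)
  lab <- ifelse(d_chip < 2, "chipboard_lt2km",
         ifelse(d_small < 4, "small_factory_lt4km", "ge4km"))
  factor(lab, levels = c("chipboard_lt2km", "small_factory_lt4km", "ge4km"))
}

# Coerce points input to an n x 2 matrix with columns x, y.
as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_km", "y_km") %in% names(points)))
      return(cbind(points$x_km, points$y_km))
    if (all(c("x", "y") %in% names(points)))
      return(cbind(points$x, points$y))
    return(as.matrix(points[, 1:2]))
  }
  m <- as.matrix(points)
  stopifnot(ncol(m) >= 2)
  m[, 1:2, drop = FALSE]
}
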