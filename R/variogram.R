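#' Variogram model
#'
#' Construct a (possibly geometrically anisotropic) variogram model
#' \eqn{\gamma(h)} with nugget \eqn{c_0}, partial sill \eqn{c} and distance
#' parameter (range) \eqn{a}. The exponential family is
#' \eqn{\gamma(h) = c_0 + c\,(1 - e^{-h/a})} for \eqn{h > 0} and
#' \eqn{\gamma(0) = 0}; "range" is the exponential distance parameter, not
#' the practical range \eqn{3a}. Anisotropy is geometric: lag vectors are
#' rotated so the major axis points `angle` degrees clockwise from north and
#' the minor axis is stretched by `1/ratio` before the isotropic form is
#' applied.
#'
#' @param family one of "exponential", "spherical", "gaussian", "nugget".
#' @param nugget nugget variance \eqn{c_0 \ge 0}.
#' @param psill partial sill \eqn{c \ge 0}.
#' @param range distance parameter \eqn{a > 0}, in km.
#' @param angle major-axis direction, degrees clockwise from north
#'   (90 = east).
#' @param ratio anisotropy ratio \eqn{\rho \in (0, 1]}; 1 = isotropic.
#' @return an object of class `vgm_model`.
#' @export
vgm_model <- function(family = c("exponential", "spherical", "gaussian", "nugget"),
                      nugget = 0, psill = 1, range = 1,
                      angle = 0, ratio = 1) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0, ratio > 0, ratio <= 1)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, angle = angle, ratio = ratio),
            class = "vgm_model")
}

#' @export
print.vgm_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, psill %.4g, range %.4g km",
              x$family, x$nugget, x$psill, x$range))
  if (x$ratio < 1)
    cat(sprintf(", anisotropy %g deg (ratio %.2f)", x$angle, x$ratio))
  cat("\n")
  invisible(x)
}

# Effective (anisotropy-corrected) distance for lag vectors (hx, hy) given
# in planar km with x = east, y = north.
aniso_distance <- function(model, hx, hy) {
  th <- model$angle * pi / 180
  major <- hx * sin(th) + hy * cos(th)
  minor <- hx * cos(th) - hy * sin(th)
  sqrt(major^2 + (minor / model$ratio)^2)
}

# Isotropic structural correlation (without sill) for effective distance h.
vgm_corr <- function(family, h, a) {
  switch(family,
    exponential = exp(-h / a),
    gaussian    = exp(-(h / a)^2),
    spherical   = ifelse(h >= a, 0, 1 - 1.5 * h / a + 0.5 * (h / a)^3),
    nugget      = ifelse(h == 0, 1, 0))
}

#' Semivariance of a variogram model
#'
#' Evaluate \eqn{\gamma(h)}. Lags may be given either as nonnegative
#' distances (taken as already anisotropy-corrected effective distances) or
#' as a two-column matrix of lag vectors `(hx, hy)` in km, to which the
#' model's geometric anisotropy is applied first. \eqn{\gamma(0) = 0} by
#' convention.
#'
#' @param model a [vgm_model()].
#' @param h numeric vector of distances, or an n x 2 matrix of lag vectors.
#' @return numeric vector of semivariances.
#' @export
semivariance <- function(model, h) {
  stopifnot(inherits(model, "vgm_model"))
  if (is.matrix(h)) {
    stopifnot(ncol(h) == 2)
    h <- aniso_distance(model, h[, 1], h[, 2])
  }
  stopifnot(all(h >= 0))
  g <- model$nugget + model$psill * (1 - vgm_corr(model$family, h, model$range))
  if (model$family == "nugget") g <- ifelse(h == 0, 0, model$nugget)
  else g[h == 0] <- 0
  g
}

# Stationary covariance implied by the model (used by the field simulator):
# C(h) = psill * corr(h) for h > 0, with the nugget as an independent
# micro-scale component added only at identical locations.
vgm_covariance <- function(model, h) {
  co <- model$psill * vgm_corr(model$family, h, model$range)
  co[h == 0] <- model$psill + model$nugget
  co
}
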