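# ray-casting point-in-polygon (polygon as closed ring of vertices)
point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Assign standardized residential exposures
#'
#' Attach per-pollutant exposures to each child's residence and standardize
#' them over the cohort (z-scores with the sample, n-1, SD). The exposure
#' source can be a kriging setup (`list(sites =, model =)` -> direct point
#' kriging at the residences, the primary path), an `exposure_surface`
#' (latent truth, used in recovery simulations), or a function mapping an
#' n x 2 coordinate matrix to values. Children outside the convex hull of
#' the monitoring sites (plus `margin_km`) are flagged as extrapolated.
#'
#' @param sources named list (names = pollutants, e.g. `hcho`, `no2`) of
#'   exposure sources as described above.
#' @param cohort data frame with `x_km`, `y_km`.
#' @param margin_km hull margin before flagging extrapolation.
#' @return `cohort` with columns `<pol>_ugm3`, `z_<pol>` and (when kriging)
#'   `extrapolated`; cohort means/SDs in attribute `standardization`.
#' @export
assign_exposure <- function(sources, cohort, margin_km = 0.5) {
  pts <- as_xy(cohort)
  std <- list()
  for (pol in names(sources)) {
    src <- sources[[pol]]
    if (is.function(src)) {
      x <- src(pts)
    } else if (inherits(src, "exposure_surface")) {
      x <- surface_value(src, pts)
    } else if (is.list(src) && !is.null(src$sites) && !is.null(src$model)) {
      kr <- krige(src$sites, src$model, pts)
      x <- kr$pred_ugm3
      sxy <- as_xy(src$sites)
      hull <- sxy[chull(sxy), , drop = FALSE]
      ctr <- colMeans(hull)
      grown <- sweep(sweep(hull, 2, ctr), 2, ctr, "+") +
        margin_km * sweep(hull, 2, ctr) /
        sqrt(rowSums(sweep(hull, 2, ctr)^2))
      out_hull <- !point_in_polygon(pts, grown)
      if (any(out_hull))
        warning(sprintf("%d residences outside the monitoring hull (+%g km); exposure extrapolated",
                        sum(out_hull), margin_km))
      cohort$extrapolated <- out_hull
    } else stop("unsupported exposure source for ", pol)
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s < 1e-12)
      stop("degenerate SD: exposure is (numerically) constant over the cohort")
    cohort[[paste0(pol, "_ugm3")]] <- x
    cohort[[paste0("z_", pol)]] <- (x - m) / s
    std[[pol]] <- c(mean = m, sd = s)
  }
  attr(cohort, "standardization") <- std
  cohort
}
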