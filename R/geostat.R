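#' Empirical (Matheron) variogram
#'
#' Method-of-moments semivariance estimator
#' \eqn{\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i - z_j)^2} over equal-width
#' distance bins. Lags can be anisotropy-corrected before binning (rotate by
#' `theta`, stretch the minor axis by `1/ratio`), which is how fixed
#' anisotropy is profiled during fitting; alternatively pairs can be
#' filtered to a direction `angle` +/- `angle_tol` for exploration.
#'
#' @param sites data frame with `x_km`, `y_km` and a value column.
#' @param value name of the value column (default `"annual_ugm3"`, falling
#'   back to `"value"`).
#' @param n_bins number of equal-width lag bins (default 12).
#' @param max_lag maximum lag (default: half the maximum pairwise distance).
#' @param theta,ratio geometric-anisotropy correction applied to lag vectors
#'   before binning (defaults: no correction).
#' @param angle,angle_tol optional directional filter (degrees clockwise
#'   from north).
#' @param min_pairs bins with fewer pairs are flagged (and ignored by the
#'   fitter).
#' @return an object of class `empirical_variogram`: data frame with `lag`
#'   (mean pair distance in bin), `center` (bin midpoint), `gamma`,
#'   `npairs`, `flagged`.
#' @export
empirical_variogram <- function(sites, value = NULL, n_bins = 12,
                                max_lag = NULL, theta = 0, ratio = 1,
                                angle = NULL, angle_tol = 22.5,
                                min_pairs = 5) {
  if (is.null(value))
    value <- if ("annual_ugm3" %in% names(sites)) "annual_ugm3" else "value"
  z <- sites[[value]]
  xy <- as_xy(sites)
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 sites")
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(2:n, function(i) i:n))
  hx <- xy[jj, 1] - xy[ii, 1]
  hy <- xy[jj, 2] - xy[ii, 2]
  if (!is.null(angle)) {
    dir <- (atan2(hx, hy) * 180 / pi) %% 180
    keep <- pmin(abs(dir - angle %% 180), 180 - abs(dir - angle %% 180)) <= angle_tol
    hx <- hx[keep]; hy <- hy[keep]; ii <- ii[keep]; jj <- jj[keep]
  }
  mdl <- vgm_model("exponential", angle = theta, ratio = ratio)
  h <- aniso_distance(mdl, hx, hy)
  sq <- 0.5 * (z[ii] - z[jj])^2
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h > 0 & h <= max_lag
  if (!any(keep)) stop("all pairs lie outside max_lag")
  h <- h[keep]; sq <- sq[keep]
  edges <- seq(0, max_lag, length.out = n_bins + 1)
  # right-closed equal-width bins (0, w], (w, 2w], ...
  bin <- pmin(pmax(ceiling(h / (max_lag / n_bins)), 1), n_bins)
  np <- tabulate(bin, nbins = n_bins)
  gam <- rep(NA_real_, n_bins)
  lag <- rep(NA_real_, n_bins)
  for (b in which(np > 0)) {
    gam[b] <- mean(sq[bin == b])
    lag[b] <- mean(h[bin == b])
  }
  out <- data.frame(lag = lag, center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    gamma = gam, npairs = np, flagged = np < min_pairs)
  structure(out, class = c("empirical_variogram", "data.frame"),
            max_lag = max_lag, theta = theta, ratio = ratio)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares with Cressie weights \eqn{N(h)/\gamma_{mod}(h)^2},
#' bounded L-BFGS-B over (nugget, partial sill, range) with multiple starts.
#' The anisotropy (theta, ratio) is taken from the empirical variogram's
#' lag correction (fixed, not optimized continuously); profiling over a
#' small anisotropy grid is done by [select_model()].
#'
#' @param emp an [empirical_variogram()].
#' @param family variogram family.
#' @param nugget_fixed optional fixed nugget value (e.g. 0).
#' @param n_starts number of optimizer starts (default 3).
#' @return a fitted [vgm_model()] with attributes `objective` and
#'   `convergence`.
#' @export
fit_variogram <- function(emp, family = "exponential", nugget_fixed = NULL,
                          n_starts = 3) {
  use <- !emp$flagged & !is.na(emp$gamma)
  if (sum(use) < 3) stop("need >= 3 populated lag bins")
  h <- emp$lag[use]; g <- emp$gamma[use]; np <- emp$npairs[use]
  theta <- attr(emp, "theta") %||% 0
  ratio <- attr(emp, "ratio") %||% 1

  if (family == "nugget") {
    c0 <- sum(np * g) / sum(np)
    m <- vgm_model("nugget", nugget = c0, psill = 0, range = 1,
                   angle = theta, ratio = ratio)
    attr(m, "objective") <- sum(np * (g - c0)^2 / max(c0, 1e-12)^2)
    attr(m, "convergence") <- 0L
    return(m)
  }

  obj <- function(par) {
    c0 <- if (is.null(nugget_fixed)) par[1] else nugget_fixed
    c1 <- par[if (is.null(nugget_fixed)) 2 else 1]
    a  <- par[if (is.null(nugget_fixed)) 3 else 2]
    gm <- c0 + c1 * (1 - vgm_corr(family, h, a))
    gm <- pmax(gm, 1e-12)
    sum(np * (g - gm)^2 / gm^2)
  }
  gmax <- max(g); lo_a <- 0.1 * min(h); hi_a <- 2 * attr(emp, "max_lag")
  starts <- list()
  base_a <- attr(emp, "max_lag") / 3
  for (f in c(1, 0.4, 2.5)) {
    s <- c(0.1 * gmax, max(gmax - 0.1 * gmax, 1e-6), min(max(base_a * f, lo_a), hi_a))
    if (!is.null(nugget_fixed)) s <- s[-1]
    starts[[length(starts) + 1]] <- s
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  lower <- c(0, 1e-9, lo_a); upper <- c(gmax * 2, gmax * 4, hi_a)
  if (!is.null(nugget_fixed)) { lower <- lower[-1]; upper <- upper[-1] }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e1,
                           parscale = pmax(abs(s), 1e-4))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed to converge from all starts")
  par <- pmin(pmax(best$par, lower), upper)
  c0 <- if (is.null(nugget_fixed)) par[1] else nugget_fixed
  c1 <- par[if (is.null(nugget_fixed)) 2 else 1]
  a  <- par[if (is.null(nugget_fixed)) 3 else 2]
  m <- vgm_model(family, nugget = c0, psill = c1, range = a,
                 angle = theta, ratio = ratio)
  attr(m, "objective") <- best$value
  attr(m, "convergence") <- best$convergence
  m
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction at query points from annual site means.
#' For each query point the ordinary-kriging system
#' \deqn{\begin{pmatrix}\Gamma & 1\\ 1^T & 0\end{pmatrix}
#'       \begin{pmatrix}w\\ \mu_L\end{pmatrix} =
#'       \begin{pmatrix}\gamma_0\\ 1\end{pmatrix}}
#' is solved, with \eqn{\Gamma_{ij} = \gamma(s_i - s_j)} from the model
#' (anisotropy applied to lag vectors). Prediction is \eqn{w^T z}; kriging
#' variance \eqn{w^T\gamma_0 + \mu_L}. Sites sharing coordinates are
#' averaged first. With zero nugget the predictor interpolates the data
#' exactly.
#'
#' @param sites data frame with `x_km`, `y_km` and annual means
#'   (`annual_ugm3` or `value`).
#' @param model a [vgm_model()].
#' @param newdata query points (data frame/matrix).
#' @param keep_weights retain the n x m weight matrix (for diagnostics).
#' @param value value column name.
#' @return an object of class `kriging_result`: data frame `x_km`, `y_km`,
#'   `pred_ugm3`, `kvar`, plus attributes `model` and optionally `weights`.
#' @export
krige <- function(sites, model, newdata, keep_weights = FALSE, value = NULL) {
  stopifnot(inherits(model, "vgm_model"))
  if (is.null(value))
    value <- if ("annual_ugm3" %in% names(sites)) "annual_ugm3" else "value"
  xy <- as_xy(sites)
  z <- sites[[value]]
  key <- paste(xy[, 1], xy[, 2])
  if (anyDuplicated(key)) {
    message("duplicate site coordinates averaged before kriging")
    agg <- aggregate(z, list(key = key), mean)
    first <- !duplicated(key)
    xy <- xy[first, , drop = FALSE]
    z <- agg$x[match(paste(xy[, 1], xy[, 2]), agg$key)]
  }
  n <- nrow(xy)
  if (n < 2) stop("need >= 2 distinct sites")
  q <- as_xy(newdata)
  m <- nrow(q)
  hx <- outer(xy[, 1], xy[, 1], "-"); hy <- outer(xy[, 2], xy[, 2], "-")
  G <- matrix(semivariance(model, cbind(as.vector(hx), as.vector(hy))), n, n)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  kap <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
  qx <- outer(xy[, 1], q[, 1], "-"); qy <- outer(xy[, 2], q[, 2], "-")
  G0 <- matrix(semivariance(model, cbind(as.vector(qx), as.vector(qy))), n, m)
  B <- rbind(G0, rep(1, m))
  W <- tryCatch(solve(A, B), error = function(e)
    stop(sprintf("singular kriging system (condition number %.3g)", kap)))
  w <- W[seq_len(n), , drop = FALSE]
  mu <- W[n + 1, ]
  pred <- drop(crossprod(w, z))
  kv <- colSums(w * G0) + mu
  kv[kv < 0 & kv > -1e-8] <- 0
  out <- data.frame(x_km = q[, 1], y_km = q[, 2], pred_ugm3 = pred, kvar = kv)
  attr(out, "model") <- model
  attr(out, "condition") <- kap
  if (keep_weights) attr(out, "weights") <- w
  class(out) <- c("kriging_result", "data.frame")
  out
}

#' Leave-one-out cross-validated RMSE
#'
#' Each site is predicted by ordinary kriging from the remaining sites with
#' a fixed variogram model; the root mean squared prediction error is
#' returned. Fails if more than 10\% of the folds fail.
#'
#' @inheritParams krige
#' @return RMSE (same units as the data) with attribute `errors`
#'   (per-site prediction errors).
#' @export
loocv_rmse <- function(sites, model, value = NULL) {
  if (is.null(value))
    value <- if ("annual_ugm3" %in% names(sites)) "annual_ugm3" else "value"
  n <- nrow(sites)
  if (n < 3) stop("need >= 3 sites for LOOCV")
  err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- tryCatch(
      krige(sites[-i, , drop = FALSE], model,
            sites[i, , drop = FALSE], value = value)$pred_ugm3,
      error = function(e) NA_real_)
    err[i] <- p - sites[[value]][i]
  }
  fail <- sum(is.na(err))
  if (fail > 0.1 * n)
    stop(sprintf("%d of %d LOOCV folds failed", fail, n))
  rmse <- sqrt(mean(err^2, na.rm = TRUE))
  attr(rmse, "errors") <- err
  rmse
}

#' Variogram model selection by LOOCV-RMSE
#'
#' Fits every candidate (family, theta, ratio) combination by
#' [empirical_variogram()] + [fit_variogram()], scores each by
#' [loocv_rmse()], and returns the minimizer. Ties are broken by fewer
#' parameters (nugget model first), then smaller range.
#'
#' @inheritParams krige
#' @param families candidate families.
#' @param theta_grid,ratio_grid anisotropy grid profiled over.
#' @param nugget_fixed optional fixed nugget.
#' @param ... passed to [empirical_variogram()].
#' @return list with `model` (best fit), `rmse`, and `leaderboard` (data
#'   frame sorted by RMSE ascending, winner first).
#' @export
select_model <- function(sites, families = c("exponential", "spherical", "gaussian"),
                         theta_grid = 0, ratio_grid = 1,
                         nugget_fixed = NULL, value = NULL, ...) {
  if (!length(families)) stop("empty candidate set")
  rows <- list(); fits <- list()
  for (fam in families) for (th in theta_grid) for (ro in ratio_grid) {
    res <- tryCatch({
      emp <- empirical_variogram(sites, value = value, theta = th, ratio = ro, ...)
      fit <- fit_variogram(emp, family = fam, nugget_fixed = nugget_fixed)
      rmse <- loocv_rmse(sites, fit, value = value)
      list(fit = fit, rmse = as.numeric(rmse))
    }, error = function(e) NULL)
    if (is.null(res)) next
    fits[[length(fits) + 1]] <- res$fit
    rows[[length(rows) + 1]] <- data.frame(
      family = fam, theta = th, ratio = ro,
      nugget = res$fit$nugget, psill = res$fit$psill, range = res$fit$range,
      n_par = if (fam == "nugget") 1L else 3L,
      loocv_rmse = res$rmse)
  }
  if (!length(rows)) stop("all candidate variogram models failed")
  lb <- do.call(rbind, rows)
  ord <- order(lb$loocv_rmse, lb$n_par, lb$range)
  lb <- lb[ord, , drop = FALSE]
  rownames(lb) <- NULL
  list(model = fits[[ord[1]]], rmse = lb$loocv_rmse[1], leaderboard = lb)
}
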