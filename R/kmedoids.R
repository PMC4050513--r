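#' Balanced k-medoids clustering of population points
#'
#' Partitioning-around-medoids variant with equal-sized clusters, as used to
#' place passive samplers at locations representative of where the sampled
#' children live. Alternates (1) a balanced assignment of points to the
#' current medoids that minimizes total point-to-medoid distance subject to
#' cluster sizes differing by at most one (solved exactly as a min-cost
#' assignment over capacity slots), and (2) a medoid update choosing, within
#' each cluster, the member with minimal summed distance to the others.
#' Initial medoids use a k-means++-style spread controlled by `seed`;
#' several starts are run and the best objective kept. Points are processed
#' in lexicographic coordinate order internally, so permuting the input
#' changes labels only, not the medoid set.
#'
#' @param points n x 2 matrix or data frame of planar km coordinates.
#' @param k number of clusters/sites.
#' @param seed integer seed for the initial medoid spread.
#' @param max_iter maximum alternation iterations per start.
#' @param n_starts number of random initialisations.
#' @return an object of class `site_plan`: `k`, `medoids` (row indices into
#'   `points`), `assignment` (cluster label per point), `sizes`, `objective`
#'   (total within-cluster distance, km), `objective_trace`, `iterations`.
#' @export
balanced_kmedoids <- function(points, k, seed = 1, max_iter = 30,
                              n_starts = 3) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (k <= 0 || k > n) stop("k must be in 1..number of points")
  if (anyDuplicated(xy)) warning("duplicate points present")
  ord <- order(xy[, 1], xy[, 2])
  p <- xy[ord, , drop = FALSE]
  D <- as.matrix(dist(p))

  base <- n %/% k
  r <- n %% k

  assign_balanced <- function(med) {
    # capacity slots: each medoid gets `base` base slots plus one extra
    # slot; k - r dummy rows may only fill extra slots, so exactly r
    # clusters end up with base + 1 real points.
    if (r == 0) {
      slots <- rep(seq_len(k), each = base)
      cost <- D[, med, drop = FALSE][, rep(seq_len(k), each = base)]
      sol <- solve_assignment(cost)
      cl <- slots[sol]
      return(cl)
    }
    slot_med <- c(rep(seq_len(k), each = base), seq_len(k))
    slot_extra <- c(rep(FALSE, k * base), rep(TRUE, k))
    m <- length(slot_med)            # = n + (k - r)
    big <- sum(D) + 1
    cost <- matrix(0, m, m)
    cost[seq_len(n), ] <- D[, med[slot_med], drop = FALSE]
    if (k - r > 0) {
      dummy <- (n + 1):m
      cost[dummy, ] <- 0
      cost[dummy, !slot_extra] <- big
    }
    sol <- solve_assignment(cost)
    slot_med[sol[seq_len(n)]]
  }

  update_medoids <- function(cl) {
    vapply(seq_len(k), function(g) {
      idx <- which(cl == g)
      s <- colSums(D[idx, idx, drop = FALSE])
      idx[which.min(s)]  # which.min takes the first = smallest sorted index
    }, integer(1))
  }

  objective <- function(cl, med) sum(D[cbind(seq_len(n), med[cl])])

  init_medoids <- function() {
    med <- integer(k)
    med[1] <- sample.int(n, 1)
    if (k > 1) {
      d2 <- D[, med[1]]^2
      for (j in 2:k) {
        if (sum(d2) > 0) {
          med[j] <- sample.int(n, 1, prob = d2 / sum(d2))
        } else {
          med[j] <- sample(setdiff(seq_len(n), med[seq_len(j - 1)]), 1)
        }
        d2 <- pmin(d2, D[, med[j]]^2)
      }
    }
    med
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    med <- init_medoids()
    trace <- numeric(0)
    cl <- NULL
    for (it in seq_len(max_iter)) {
      cl_new <- assign_balanced(med)
      obj <- objective(cl_new, med)
      trace <- c(trace, obj)
      med_new <- update_medoids(cl_new)
      if (!is.null(cl) && identical(sort(med_new), sort(med)) &&
          identical(cl_new, cl)) { cl <- cl_new; break }
      cl <- cl_new
      if (identical(sort(med_new), sort(med))) break
      med <- med_new
    }
    med <- update_medoids(cl)
    obj <- objective(cl, med)
    trace <- c(trace, obj)
    if (is.null(best) || obj < best$objective - 1e-12)
      best <- list(medoids = med, assignment = cl, objective = obj,
                   trace = trace, iterations = it)
  }

  # canonical cluster labels: order clusters by their medoid's sorted index
  lab_order <- order(best$medoids)
  relabel <- match(seq_len(k), lab_order)
  cl_sorted <- relabel[best$assignment]
  med_sorted <- best$medoids[lab_order]

  # map back to original row order
  assignment <- integer(n)
  assignment[ord] <- cl_sorted
  medoids <- ord[med_sorted]
  structure(list(k = k, medoids = medoids, assignment = assignment,
                 sizes = as.integer(table(factor(assignment, levels = seq_len(k)))),
                 objective = best$objective,
                 objective_trace = best$trace,
                 iterations = best$iterations),
            class = "site_plan")
}

#' @export
print.site_plan <- function(x, ...) {
  cat(sprintf("site plan: k = %d, objective = %.3f km, sizes %s\n",
              x$k, x$objective, paste(range(x$sizes), collapse = "-")))
  invisible(x)
}

#' Stratified monitoring-network design
#'
#' Place half (or `inner_fraction`) of the monitoring sites among the
#' population points within `radius_km` of a chipboard industry, where the
#' highest concentrations are expected, and the remainder among the points
#' outside, each half by [balanced_kmedoids()].
#'
#' @param points population points (children's residences), n x 2.
#' @param industry_points chipboard-industry coordinates, m x 2.
#' @param k total number of sites (default 62).
#' @param inner_fraction fraction of sites allocated inside the radius.
#' @param radius_km radius around the industries (default 3 km).
#' @param seed,max_iter,n_starts passed to [balanced_kmedoids()].
#' @return a `site_plan` over all points, with an extra `inner` logical per
#'   medoid.
#' @export
stratified_site_split <- function(points, industry_points, k = 62,
                                  inner_fraction = 0.5, radius_km = 3,
                                  seed = 1, max_iter = 30, n_starts = 3) {
  stopifnot(inner_fraction >= 0, inner_fraction <= 1)
  xy <- as_xy(points)
  n <- nrow(xy)
  if (k > n) stop("k exceeds the number of points")
  d <- min_dist_to(xy, as_xy(industry_points))
  inner <- d <= radius_km
  k_in <- ceiling(inner_fraction * k)
  k_out <- k - k_in
  if (k_in > 0 && sum(inner) == 0)
    stop(sprintf("no points within %g km of an industry but %d sites allocated",
                 radius_km, k_in))
  if (k_out > 0 && sum(!inner) == 0)
    stop(sprintf("no points outside %g km of the industries but %d sites allocated",
                 radius_km, k_out))
  if (k_in > sum(inner) || k_out > sum(!inner))
    stop(sprintf("allocation infeasible: %d/%d sites for %d/%d points",
                 k_in, k_out, sum(inner), sum(!inner)))

  if (k_in == 0) {
    plan <- balanced_kmedoids(xy, k, seed = seed, max_iter = max_iter,
                              n_starts = n_starts)
    plan$inner <- rep(FALSE, k)
    return(plan)
  }
  if (k_out == 0) {
    plan <- balanced_kmedoids(xy, k, seed = seed, max_iter = max_iter,
                              n_starts = n_starts)
    plan$inner <- rep(TRUE, k)
    return(plan)
  }
  pi_in <- balanced_kmedoids(xy[inner, , drop = FALSE], k_in, seed = seed,
                             max_iter = max_iter, n_starts = n_starts)
  pi_out <- balanced_kmedoids(xy[!inner, , drop = FALSE], k_out,
                              seed = seed + 1, max_iter = max_iter,
                              n_starts = n_starts)
  idx_in <- which(inner); idx_out <- which(!inner)
  assignment <- integer(n)
  assignment[idx_in] <- pi_in$assignment
  assignment[idx_out] <- k_in + pi_out$assignment
  medoids <- c(idx_in[pi_in$medoids], idx_out[pi_out$medoids])
  structure(list(k = k, medoids = medoids, assignment = assignment,
                 sizes = as.integer(table(factor(assignment, levels = seq_len(k)))),
                 objective = pi_in$objective + pi_out$objective,
                 objective_trace = NULL,
                 iterations = max(pi_in$iterations, pi_out$iterations),
                 inner = c(rep(TRUE, k_in), rep(FALSE, k_out))),
            class = "site_plan")
}

#' Site table from a plan
#'
#' @param plan a `site_plan`.
#' @param points the points the plan was built from.
#' @return data frame `site_id`, `x_km`, `y_km`, `cluster_size`.
#' @export
site_table <- function(plan, points) {
  xy <- as_xy(points)
  data.frame(site_id = sprintf("S%02d", seq_len(plan$k)),
             x_km = xy[plan$medoids, 1],
             y_km = xy[plan$medoids, 2],
             cluster_size = plan$sizes)
}
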