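# Small fixtures and independent oracles used across the suite.

tiny_district <- function() {
  district_spec(extent = c(xmin = 0, xmax = 20, ymin = 0, ymax = 30))
}

# Brute-force ordinary-kriging weights by direct numerical minimization of
# the prediction variance 2 w'g0 - w'G w subject to sum(w) = 1 (the last
# weight is eliminated). Independent of the linear-system solver.
ok_weights_bruteforce <- function(sites_xy, model, query) {
  n <- nrow(sites_xy)
  hx <- outer(sites_xy[, 1], sites_xy[, 1], "-")
  hy <- outer(sites_xy[, 2], sites_xy[, 2], "-")
  G <- matrix(semivariance(model, cbind(as.vector(hx), as.vector(hy))), n, n)
  g0 <- semivariance(model, cbind(sites_xy[, 1] - query[1],
                                  sites_xy[, 2] - query[2]))
  pv <- function(wfree) {
    w <- c(wfree, 1 - sum(wfree))
    2 * sum(w * g0) - drop(t(w) %*% G %*% w)
  }
  init <- rep(1 / n, n - 1)
  o <- optim(init, pv, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  c(o$par, 1 - sum(o$par))
}

# Exhaustive optimum over all balanced partitions with medoid centers
# (feasible for n <= 8, k <= 3). Objective: total distance to the cluster
# medoid, medoid = member minimizing the in-cluster distance sum.
balanced_kmedoids_bruteforce <- function(xy, k) {
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  best <- Inf
  cluster_cost <- function(idx) {
    s <- colSums(D[idx, idx, drop = FALSE])
    min(s)
  }
  rec <- function(remaining, size_left) {
    if (!length(size_left)) return(0)
    s <- size_left[1]
    # anchor the smallest remaining index to kill permutation symmetry
    a <- remaining[1]
    rest <- remaining[-1]
    if (s - 1 > length(rest)) return(Inf)
    combs <- if (s - 1 == 0) list(integer(0))
    else if (length(rest) == 1) list(rest)   # combn(n, 1) scalar trap
    else utils::combn(rest, s - 1, simplify = FALSE)
    m <- Inf
    for (cb in combs) {
      idx <- c(a, cb)
      m <- min(m, cluster_cost(idx) +
                 rec(setdiff(remaining, idx), size_left[-1]))
    }
    m
  }
  # sizes may be assigned to clusters in any order; with distinct sizes the
  # anchoring trick needs every size multiset ordering; enumerate unique
  # permutations of sizes.
  size_perms <- unique(combinat_perms(sizes))
  for (sp in size_perms) best <- min(best, rec(seq_len(n), sp))
  best
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Quick standardized-exposure matrix for association unit tests.
fake_exposed_cohort <- function(n, seed) {
  co <- generate_cohort(tiny_district(), ceiling(n / 3), seed = seed)
  co <- co[seq_len(n), , drop = FALSE]
  set.seed(seed + 987654)
  x1 <- rnorm(n); x2 <- rnorm(n)
  co$z_hcho <- (x1 - mean(x1)) / sd(x1)
  co$z_no2 <- (x2 - mean(x2)) / sd(x2)
  co
}
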