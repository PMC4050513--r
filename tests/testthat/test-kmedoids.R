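test_that("square corners with k = n make every point its own medoid", {
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  plan <- balanced_kmedoids(pts, 4, seed = 1)
  expect_setequal(plan$medoids, 1:4)
  expect_equal(plan$objective, 0)
  expect_equal(plan$sizes, rep(1L, 4))
})

test_that("two tight triads far apart split into the triads", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
               c(10, 10), c(10.1, 10), c(10, 10.1))
  plan <- balanced_kmedoids(pts, 2, seed = 1)
  expect_equal(sort(plan$sizes), c(3L, 3L))
  expect_length(unique(plan$assignment[1:3]), 1)
  expect_length(unique(plan$assignment[4:6]), 1)
  expect_false(plan$assignment[1] == plan$assignment[4])
  # matches the exhaustive optimum over balanced 2-partitions
  expect_equal(plan$objective, balanced_kmedoids_bruteforce(pts, 2),
               tolerance = 1e-12)
})

test_that("cluster sizes always differ by at most one", {
  set.seed(4)
  for (case in list(c(100, 10), c(23, 4), c(17, 5), c(9, 2))) {
    pts <- cbind(runif(case[1], 0, 20), runif(case[1], 0, 30))
    plan <- balanced_kmedoids(pts, case[2], seed = 7)
    expect_lte(diff(range(plan$sizes)), 1)
    expect_equal(sum(plan$sizes), case[1])
    # each medoid belongs to its own cluster
    expect_true(all(plan$assignment[plan$medoids] == seq_len(case[2])))
  }
})

test_that("objective matches exhaustive enumeration for small problems", {
  set.seed(11)
  for (i in 1:6) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    plan <- balanced_kmedoids(pts, k, seed = i, n_starts = 5)
    expect_equal(plan$objective, balanced_kmedoids_bruteforce(pts, k),
                 tolerance = 1e-10, info = sprintf("n=%d k=%d", n, k))
  }
})

test_that("objective trace is nonincreasing and terminates", {
  set.seed(2)
  pts <- cbind(runif(60, 0, 20), runif(60, 0, 30))
  plan <- balanced_kmedoids(pts, 6, seed = 3, n_starts = 1, max_iter = 25)
  expect_true(all(diff(plan$objective_trace) <= 1e-9))
  expect_lte(plan$iterations, 25)
})

test_that("permuting the input changes labels but not the medoid set", {
  set.seed(5)
  pts <- cbind(runif(30, 0, 20), runif(30, 0, 30))
  perm <- sample(30)
  p1 <- balanced_kmedoids(pts, 5, seed = 9)
  p2 <- balanced_kmedoids(pts[perm, ], 5, seed = 9)
  m1 <- pts[p1$medoids, ]
  m2 <- pts[perm, ][p2$medoids, ]
  expect_equal(m1[order(m1[, 1], m1[, 2]), ], m2[order(m2[, 1], m2[, 2]), ])
})

test_that("argument errors are raised", {
  pts <- cbind(1:5, 1:5)
  expect_error(balanced_kmedoids(pts, 0))
  expect_error(balanced_kmedoids(pts, 6))
})

test_that("stratified split allocates half the sites near the industries", {
  d <- tiny_district()
  co <- generate_cohort(d, 60, seed = 21)
  plan <- stratified_site_split(co, d$chipboard, k = 20, seed = 2)
  sites <- site_table(plan, co)
  d_ind <- genokrig:::min_dist_to(cbind(sites$x_km, sites$y_km), d$chipboard)
  expect_gte(sum(d_ind <= 3), 10)
  expect_equal(plan$k, 20)
  # balance holds within each half of the split
  expect_lte(diff(range(plan$sizes[plan$inner])), 1)
  expect_lte(diff(range(plan$sizes[!plan$inner])), 1)
})

test_that("inner_fraction 0 reduces to plain balanced k-medoids", {
  set.seed(8)
  pts <- cbind(runif(40, 10, 20), runif(40, 20, 30))  # all far from industry
  ind <- rbind(c(0, 0))
  p0 <- stratified_site_split(pts, ind, k = 4, inner_fraction = 0, seed = 5)
  pk <- balanced_kmedoids(pts, 4, seed = 5)
  expect_equal(sort(p0$medoids), sort(pk$medoids))
  expect_equal(p0$objective, pk$objective)
})
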