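# small planar MRF fixture: two seed clusters with a strip of free points
mrf_fixture <- function(n_free = 6, gamma = 1, tau = 1, phi = 1, k = 3,
                        jitter_seed = 1) {
  set.seed(jitter_seed)
  seeds_a <- cbind(runif(3, 0, 5), runif(3, 0, 5), 0)
  seeds_b <- cbind(runif(3, 45, 50), runif(3, 0, 5), 0)
  free <- cbind(runif(n_free, 10, 40), runif(n_free, 0, 5), 0)
  pc <- labeled_cloud(rbind(free, seeds_a, seeds_b))
  pc$normals <- matrix(rep(c(0, 0, 1), n_points(pc)), ncol = 3, byrow = TRUE)
  mrf_problem(pc, instance_ids = c(4L, 9L), roi = seq_len(n_free),
              seeds = list(n_free + 1:3, n_free + 4:6),
              gamma = gamma, tau = tau, phi = phi, k = k)
}

test_that("problem construction fixes seeds and computes d_prime", {
  pr <- mrf_fixture(n_free = 10)
  expect_equal(pr$n_free, 10L)
  expect_identical(pr$roi, 1:10)
  # d' equals the largest edge length (exhaustive re-scan)
  pts <- pr$cloud$coords[pr$nodes, ]
  d <- sqrt(rowSums((pts[pr$edges[, 1], ] - pts[pr$edges[, 2], ])^2))
  expect_equal(pr$d_prime, max(d))
  # seeds are removed from the roi
  pr2 <- mrf_problem(pr$cloud, c(4L, 9L), roi = c(1:10, 11L),
                     seeds = list(11:13, 14:16))
  expect_identical(pr2$roi, 1:10)
  expect_error(mrf_problem(pr$cloud, c(4L, 9L), 1:10,
                           seeds = list(11:13, integer(0))), "empty seed")
})

test_that("k=1 chain graph links each node to its nearest neighbour", {
  coords <- cbind(c(0, 1, 2.5, 4.5, 7), 0, 0)
  pc <- labeled_cloud(rbind(coords, c(-5, 0, 0), c(12, 0, 0)))
  pc$normals <- matrix(rep(c(0, 0, 1), 7), ncol = 3, byrow = TRUE)
  pr <- mrf_problem(pc, c(1L, 2L), roi = 1:5, seeds = list(6L, 7L), k = 1)
  # brute-force 1-NN edges over the node set, symmetrised
  nodes <- pr$nodes
  pts <- pc$coords[nodes, ]
  nn1 <- unname(brute_knn(pts, pts, 2)[, 2])
  want <- unique(t(apply(cbind(seq_along(nodes), nn1), 1, sort)))
  got <- pr$edges[order(pr$edges[, 1], pr$edges[, 2]), ]
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
})

test_that("energy matches a hand-expanded sum on a 4-point toy problem", {
  # two free points between one seed of each label, all on a line, flat normals
  pc <- labeled_cloud(cbind(c(1, 2, 0, 3), 0, 0))
  pc$normals <- matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE)
  pr <- mrf_problem(pc, c(1L, 2L), roi = 1:2, seeds = list(3L, 4L),
                    gamma = 2, tau = 1, phi = 1, k = 3)
  # normals identical -> angle 0 -> every V factor is 0: energy is data only
  e <- mrf_energy(pr, c(1L, 2L))
  expect_equal(e, 2 * (1 + 1))  # |1-0| = 1 to seed A, |3-2| = 1 to seed B
  e2 <- mrf_energy(pr, c(2L, 2L))
  expect_equal(e2, 2 * (2 + 1))
})

test_that("V edge cases: unity distance factor, folded angle, Potts gating", {
  # square layout, free points 10 apart (the largest graph edge, so d'=10)
  # with orthogonal normals: folded angle pi/2 -> angle factor 1/2
  pc <- labeled_cloud(rbind(c(0, 0, 0), c(10, 0, 0),
                            c(0, -1, 0), c(10, -1, 0)))
  pc$normals <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1), c(1, 0, 0))
  pr <- mrf_problem(pc, c(1L, 2L), roi = 1:2, seeds = list(3L, 4L),
                    gamma = 1, tau = 1, phi = 1, k = 2)
  expect_equal(pr$d_prime, 10)
  # hand expansion: edges {1,3} d=1, {1,2} d=10, {2,4} d=1, {3,4} d=10;
  # the fixed seed pair {3,4} always disagrees and costs (10/10)*(1/2)
  e_diff <- mrf_energy(pr, c(1L, 2L))
  expect_equal(e_diff, (1 + 1) + 0.5 + 0.5, tolerance = 1e-12)
  # same-label free points: only the free2-seedB edge disagrees, and its
  # angle factor is 0 (parallel normals), so V vanishes there (Potts gating
  # leaves the data term plus the constant seed-seed cut)
  e_same <- mrf_energy(pr, c(1L, 1L))
  expect_equal(e_same, (1 + sqrt(101)) + 0 + 0.5, tolerance = 1e-12)
})

test_that("alpha-expansion reaches the exhaustive minimum on small problems", {
  set.seed(55)
  for (case in 1:25) {
    n_lab <- sample(2:3, 1)
    n_free <- sample(4:8, 1)
    pts <- matrix(runif((n_free + 2 * n_lab) * 3, 0, 20), ncol = 3)
    pc <- labeled_cloud(pts)
    pc$normals <- shootseg:::.row_unit(matrix(rnorm(3 * n_points(pc)), ncol = 3))
    ids <- seq_len(n_lab)
    seeds <- split(n_free + seq_len(2 * n_lab),
                   rep(seq_len(n_lab), each = 2))
    pr <- mrf_problem(pc, ids, roi = seq_len(n_free), seeds = seeds,
                      gamma = runif(1, 0.05, 2), k = 4)
    sol <- solve_mrf(pr)
    expect_lte(sol$energy, sol$initial_energy)
    expect_equal(sol$energy, exhaustive_mrf_min(pr), tolerance = 1e-9)
  }
})

test_that("a dominant data term yields pure nearest-seed labeling", {
  pr <- mrf_fixture(n_free = 12, gamma = 1e6, jitter_seed = 3)
  sol <- solve_mrf(pr)
  nearest <- pr$instance_ids[apply(pr$data, 1, which.min)]
  expect_identical(sol$labeling, nearest)
})

test_that("the label boundary settles on a synthetic crease", {
  # a roof: two planar sheets meeting at x = 0 with a 90-degree normal change
  set.seed(66)
  nx <- 60
  x <- runif(nx, -30, 30)
  y <- runif(nx, 0, 30)
  z <- -abs(x)  # crease along x = 0
  pc <- labeled_cloud(cbind(x, y, z))
  pc <- estimate_normals(pc, k = 6)
  left_seed <- which.min(x); right_seed <- which.max(x)
  roi <- setdiff(seq_len(nx), c(left_seed, right_seed))
  pr <- mrf_problem(pc, c(1L, 2L), roi = roi,
                    seeds = list(left_seed, right_seed),
                    gamma = 0.05, tau = 1, phi = 1, k = 6)
  sol <- solve_mrf(pr)
  lab <- integer(nx)
  lab[roi] <- sol$labeling; lab[left_seed] <- 1L; lab[right_seed] <- 2L
  # boundary edges (disagreeing labels) carry larger normal angles than
  # interior edges: the cut prefers the crease
  nodes <- pr$nodes
  lab_n <- lab[nodes]
  nrm <- pc$normals[nodes, ]
  ang <- acos(pmin(abs(rowSums(nrm[pr$edges[, 1], ] * nrm[pr$edges[, 2], ])), 1))
  disagree <- lab_n[pr$edges[, 1]] != lab_n[pr$edges[, 2]]
  expect_gt(mean(ang[disagree]), mean(ang[!disagree]))
  # and the two sides are dominated by their own seed labels
  expect_gt(mean(lab[x < -3] == 1L), 0.8)
  expect_gt(mean(lab[x > 3] == 2L), 0.8)
})

test_that("direct label assignment is a clean idempotent bulk relabel", {
  sh <- toy_shoot()
  state <- segmentation_state(sh$cloud,
                              list(sh$stem, sh$leaf_a, sh$leaf_b),
                              c("stem", "leaf", "leaf"))
  roi <- sh$leaf_b[1:5]
  st2 <- assign_label_direct(state, roi, 2L)
  expect_true(all(st2$cloud$labels[roi] == 2L))
  check_partition(st2)
  st3 <- assign_label_direct(st2, roi, 2L)
  expect_identical(st3$cloud$labels, st2$cloud$labels)
  expect_error(assign_label_direct(state, roi, 9L), "unknown instance")
  expect_error(assign_label_direct(state, integer(0), 2L), "nonempty")
})
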