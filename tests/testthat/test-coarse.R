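# --- pot and seed detection -------------------------------------------------

test_that("pot detection uses a strict below-stem threshold", {
  sh <- toy_shoot()
  expect_length(detect_pot(sh$cloud, sh$stem), 0L)

  set.seed(17)
  coords <- rbind(sh$cloud$coords,
                  cbind(runif(10, -30, 30), runif(10, -30, 30),
                        runif(10, -50, -1)),
                  c(10, 10, 0))  # exactly at the stem minimum -> NOT pot
  pc <- labeled_cloud(coords)
  pot <- detect_pot(pc, sh$stem)   # toy shoot has 51 points
  expect_identical(pot, 52:61)
  expect_false(62L %in% pot)
})

test_that("seed detection finds separated tips, one per organ", {
  # two leaf tips 300 mm apart plus descending flank points
  tips <- rbind(c(0, 200, 300), c(150, -100, 280))
  flank <- rbind(cbind(0, 200 - 1:8 * 10, 300 - 1:8 * 10),
                 cbind(150, -100 + 1:8 * 10, 280 - 1:8 * 10))
  pc <- labeled_cloud(rbind(tips, flank))
  seeds <- detect_organ_seeds(pc, min_sep = 50)
  expect_equal(seeds$point, c(1L, 2L))
  expect_equal(seeds$id, c(2L, 3L))

  # one cluster -> exactly one seed, the argmax z
  one <- labeled_cloud(cbind(runif(40), runif(40), sort(runif(40, 0, 30))))
  s1 <- detect_organ_seeds(one, min_sep = 50)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$point, 40L)
})

test_that("a decoy maximum 30 mm from a true tip is suppressed", {
  tips <- rbind(c(0, 0, 300), c(200, 0, 280))
  decoy <- c(30, 0, 295)  # 30 mm from tip 1, lower
  flank <- rbind(cbind(0, 1:8 * 10, 300 - 1:8 * 8),
                 cbind(200, 1:8 * 10, 280 - 1:8 * 8))
  pc <- labeled_cloud(rbind(tips, decoy, flank))
  seeds <- detect_organ_seeds(pc, min_sep = 50)
  expect_equal(sort(seeds$point), c(1L, 2L))
  expect_false(3L %in% seeds$point)
})

test_that("seed detection recovers generator tips exactly on noiseless shoots", {
  for (seed in c(2, 8)) {
    sh <- generate_shoot(shoot_spec(n_leaves = 6, noise_sd_mm = 0,
                                    rng_seed = seed))
    truth_stem <- which(sh$cloud$labels == 1L)
    truth_pot <- which(sh$cloud$labels == max(sh$cloud$labels))
    seeds <- detect_organ_seeds(sh$cloud, exclude = c(truth_stem, truth_pot))
    expect_identical(sort(seeds$point), sort(sh$seeds$point))
    # ids follow descending height, matching the generator's ordering
    expect_identical(seeds$point, sh$seeds$point)
  }
})

# --- Sinkhorn ---------------------------------------------------------------

test_that("2-point plan matches the closed-form entropic solution", {
  pl <- sinkhorn_plan(rbind(c(0, 0, 0), c(1, 0, 0)), epsilon = 5)
  expect_equal(unname(pl$plan), closed_form_2pt(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  off <- 0.5 * exp(-5) / (1 + exp(-5))
  expect_equal(ot_distance(pl, 1, 2), 1 / off, tolerance = 1e-6)
  # self-distance is the smallest in its row
  expect_lt(ot_distance(pl, 1, 1), ot_distance(pl, 1, 2))
})

test_that("plan marginals and symmetry hold across sizes", {
  set.seed(31)
  for (n in c(10, 200)) {
    x <- matrix(runif(n * 3, 0, 100), ncol = 3)
    pl <- sinkhorn_plan(x, epsilon = 5)
    m <- plan_marginals(pl)
    expect_lt(max(abs(m$rows - 1 / n)), 1e-6)
    expect_lt(max(abs(m$cols - 1 / n)), 1e-6)
    expect_lt(max(abs(pl$plan - t(pl$plan))), 1e-8)
    expect_true(all(pl$plan > 0))
  }
})

test_that("log-domain scaling reaches the same fixed point", {
  set.seed(32)
  x <- matrix(runif(24, 0, 10), ncol = 3)
  pl <- sinkhorn_plan(x, epsilon = 5)
  H <- as.matrix(dist(x)); H <- H / max(H)
  res <- shootseg:::.sinkhorn_log(H, 5, rep(1 / 8, 8), 10000L, 1e-12)
  expect_equal(res$plan, pl$plan, tolerance = 1e-8)
})

test_that("the plan minimises the entropic energy over feasible couplings", {
  set.seed(33)
  n <- 20
  eps <- 5
  x <- matrix(runif(n * 3, 0, 50), ncol = 3)
  pl <- sinkhorn_plan(x, eps)
  H <- pl$cost
  energy <- function(m) sum(m * H) + sum(m * log(m)) / eps
  e_star <- energy(pl$plan)
  # independent coupling
  indep <- matrix(1 / n^2, n, n)
  expect_lte(e_star, energy(indep) + 1e-12)
  # 1000 random couplings projected onto the marginals by repeated scaling
  worse <- vapply(seq_len(1000), function(i) {
    m <- matrix(rexp(n * n), n, n)
    for (it in 1:200) {
      m <- m / rowSums(m) / n
      m <- t(t(m) / colSums(m)) / n
    }
    energy(m)
  }, numeric(1))
  expect_true(all(e_star <= worse + 1e-10))
})

test_that("ot_distance is antitone in plan mass and guards coverage", {
  set.seed(34)
  x <- matrix(runif(30, 0, 10), ncol = 3)
  pl <- sinkhorn_plan(x, epsilon = 5)
  m <- pl$plan[1, ]
  d <- vapply(1:10, function(v) ot_distance(pl, 1, v), numeric(1))
  expect_identical(order(m), order(-d))
  expect_error(ot_distance(pl, 1, 99), "not covered")
})

# --- top-down assignment ----------------------------------------------------

test_that("a point coincident with a seed joins that seed's instance", {
  sh <- toy_shoot()
  cl <- sh$cloud
  cl$labels <- rep(-1L, n_points(cl))
  seeds <- shootseg:::.seed_set(point = c(22L, 37L), id = c(2L, 3L),
                                role = c("organ", "organ"),
                                z = cl$coords[c(22, 37), 3], min_sep = 50)
  state <- initialize_state(cl, sh$stem, integer(0), seeds)
  pl <- sinkhorn_plan(cl$coords, epsilon = 5)
  out <- assign_top_down(state, pl)
  expect_length(out$unsegmented, 0L)
  check_partition(out)
  expect_equal(out$cloud$labels[22], 2L)
  expect_equal(out$cloud$labels[37], 3L)
})

test_that("assignment equals the step-by-step brute-force replay", {
  sh <- toy_shoot()
  cl <- sh$cloud
  cl$labels <- rep(-1L, n_points(cl))
  seeds <- shootseg:::.seed_set(point = c(22L, 37L), id = c(2L, 3L),
                                role = c("organ", "organ"),
                                z = cl$coords[c(22, 37), 3], min_sep = 50)
  state <- initialize_state(cl, sh$stem, integer(0), seeds)
  pl <- sinkhorn_plan(cl$coords, epsilon = 5)

  out <- assign_top_down(state, pl)
  # oracle: recompute argmin over the full D_s matrix at every step
  Ds <- 1 / pl$plan
  replay <- replay_top_down(cl$coords,
                            list(sh$stem, 22L, 37L),
                            setdiff(seq_len(n_points(cl)), c(sh$stem, 22L, 37L)),
                            Ds)
  expect_identical(out$cloud$labels, as.integer(replay))

  # the two well-separated leaves each rejoin their own tip's instance
  expect_true(all(out$cloud$labels[sh$leaf_a] == 2L))
  expect_true(all(out$cloud$labels[sh$leaf_b] == 3L))

  # euclidean variant agrees with its own replay too
  out_e <- assign_top_down(state, method = "euclidean")
  De <- as.matrix(dist(cl$coords))
  replay_e <- replay_top_down(cl$coords, list(sh$stem, 22L, 37L),
                              setdiff(seq_len(n_points(cl)),
                                      c(sh$stem, 22L, 37L)), De)
  expect_identical(out_e$cloud$labels, as.integer(replay_e))
})

test_that("assignment is deterministic", {
  sh <- generate_shoot(shoot_spec(n_leaves = 5, points_per_organ = 60,
                                  rng_seed = 12))
  r1 <- run_pipeline(sh$cloud, stem = sh$stem)
  r2 <- run_pipeline(sh$cloud, stem = sh$stem)
  expect_identical(r1$cloud$labels, r2$cloud$labels)
})
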