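#' Specification of a synthetic maize-like shoot
#'
#' Parametric description of a single-stemmed shoot used to generate labeled
#' ground-truth clouds for testing: one tapered, optionally bowed stem; 4-15
#' leaves attached at increasing heights, each a curved ribbon whose highest
#' point sits over the mid-blade (lower leaves) and whose tip droops; an
#' optional tassel (central spike plus short branches), ear (ellipsoid on the
#' mid stem) and pot (disk plus cylindrical wall strictly below the stem
#' base). Organ highest points are kept pairwise more than 50 mm apart by
#' construction -- the working assumption of the seed detector -- and a
#' generation error is raised otherwise.
#'
#' Defaults emulate a vegetative (V6-V13-like) potted shoot at scanner scale:
#' 800 mm stem tapering 12 -> 6 mm radius with an 8 mm bow, 500 x 60 mm
#' leaves with alternate (180 degree) phyllotaxy and mild azimuth jitter, and
#' 1 mm Gaussian coordinate noise approximating multi-view-stereo
#' reconstruction jitter.
#'
#' @param n_leaves number of leaves (>= 1, realistically 4-15).
#' @param stem_height_mm stem height.
#' @param stem_radius_bottom_mm,stem_radius_top_mm stem taper radii.
#' @param stem_curvature bow amplitude of the stem centreline (mm).
#' @param leaf_length_mm,leaf_width_mm leaf blade dimensions.
#' @param leaf_arc droop curvature multiplier (1 = default droop).
#' @param phyllotaxy_deg azimuth increment between successive leaves.
#' @param azimuth_jitter_deg uniform jitter on each leaf azimuth.
#' @param include_tassel,include_ear,include_pot organ toggles.
#' @param points_per_organ sampled points per organ.
#' @param noise_sd_mm additive Gaussian coordinate noise (sd, mm).
#' @param rng_seed integer seed; identical specs generate identical clouds.
#' @return an object of class `shoot_spec`.
#' @export
shoot_spec <- function(n_leaves = 9L,
                       stem_height_mm = 800,
                       stem_radius_bottom_mm = 12,
                       stem_radius_top_mm = 6,
                       stem_curvature = 8,
                       leaf_length_mm = 500,
                       leaf_width_mm = 60,
                       leaf_arc = 1,
                       phyllotaxy_deg = 180,
                       azimuth_jitter_deg = 15,
                       include_tassel = FALSE,
                       include_ear = FALSE,
                       include_pot = TRUE,
                       points_per_organ = 250L,
                       noise_sd_mm = 1,
                       rng_seed = 1L) {
  if (n_leaves < 1L) stop("n_leaves must be >= 1")
  if (points_per_organ < 10L) stop("points_per_organ must be >= 10")
  if (noise_sd_mm < 0) stop("noise_sd_mm must be nonnegative")
  structure(
    list(n_leaves = as.integer(n_leaves),
         stem_height_mm = stem_height_mm,
         stem_radius_bottom_mm = stem_radius_bottom_mm,
         stem_radius_top_mm = stem_radius_top_mm,
         stem_curvature = stem_curvature,
         leaf_length_mm = leaf_length_mm,
         leaf_width_mm = leaf_width_mm,
         leaf_arc = leaf_arc,
         phyllotaxy_deg = phyllotaxy_deg,
         azimuth_jitter_deg = azimuth_jitter_deg,
         include_tassel = isTRUE(include_tassel),
         include_ear = isTRUE(include_ear),
         include_pot = isTRUE(include_pot),
         points_per_organ = as.integer(points_per_organ),
         noise_sd_mm = noise_sd_mm,
         rng_seed = as.integer(rng_seed)),
    class = "shoot_spec"
  )
}

# run expr under a private RNG stream seeded with `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a labeled synthetic shoot
#'
#' Samples the shoot described by `spec`, assigns ground-truth instance
#' labels (stem = 1, leaves bottom-up from 2, then tassel, ear, and pot as
#' the last id), and records per-organ highest points for oracle use. Noise
#' is added after the highest points are identified, so with
#' `noise_sd_mm = 0` every organ's max-z point is exactly its recorded seed.
#'
#' @param spec a [shoot_spec()].
#' @return list with `cloud` (labeled [labeled_cloud()]), `seeds` (true organ
#'   highest points as a `seed_set`), `stem` (a [stem_params()] with the true
#'   endpoints and a radius suited to the taper), `roles` (per instance id)
#'   and `tips` (matrix of the noiseless organ highest-point coordinates).
#' @export
generate_shoot <- function(spec = shoot_spec()) {
  stopifnot(inherits(spec, "shoot_spec"))
  .with_seed(spec$rng_seed, {
    H <- spec$stem_height_mm
    npo <- spec$points_per_organ
    organs <- list()

    # stem: tapered tube, centreline bowed in x and returning to the axis
    t <- sort(runif(npo))
    th <- runif(npo, 0, 2 * pi)
    r <- spec$stem_radius_bottom_mm +
      (spec$stem_radius_top_mm - spec$stem_radius_bottom_mm) * t
    ctr <- cbind(spec$stem_curvature * sin(pi * t), 0, t * H)
    organs[[1]] <- list(
      pts = ctr + cbind(r * cos(th), r * sin(th), 0),
      role = "stem"
    )

    stem_center <- function(tt) {
      c(spec$stem_curvature * sin(pi * tt), 0, tt * H)
    }
    stem_radius <- function(tt) {
      spec$stem_radius_bottom_mm +
        (spec$stem_radius_top_mm - spec$stem_radius_bottom_mm) * tt
    }

    # leaves: ribbons on a parabolic height profile rel(s) = c1 s - c2 s^2
    c1 <- 0.7
    c2 <- c1 + 0.28 * spec$leaf_arc
    attach_t <- seq(0.25, 0.95, length.out = spec$n_leaves)
    L <- spec$leaf_length_mm
    for (i in seq_len(spec$n_leaves)) {
      az <- ((i - 1) * spec$phyllotaxy_deg +
               runif(1, -1, 1) * spec$azimuth_jitter_deg) * pi / 180
      d <- c(cos(az), sin(az), 0)
      w <- c(-sin(az), cos(az), 0)
      base <- stem_center(attach_t[i]) +
        d * (stem_radius(attach_t[i]) + 2)
      s <- runif(npo)
      lat <- runif(npo, -0.5, 0.5) * spec$leaf_width_mm * (1 - 0.7 * s)
      pts <- rep(base, each = npo) +
        outer(0.8 * L * s, d) + outer(lat, w) +
        outer(L * (c1 * s - c2 * s^2), c(0, 0, 1))
      organs[[length(organs) + 1L]] <- list(pts = pts, role = "leaf")
    }

    if (spec$include_tassel) {
      base <- stem_center(1)
      n_c <- ceiling(0.4 * npo)
      n_b <- npo - n_c
      sc <- runif(n_c)
      central <- rep(base, each = n_c) +
        cbind(rnorm(n_c, 0, 3), rnorm(n_c, 0, 3), 130 * sc)
      bid <- sample.int(4, n_b, replace = TRUE)
      sb <- runif(n_b)
      azb <- (bid - 1) * pi / 2 + pi / 6
      el <- 75 * pi / 180
      branch <- rep(base, each = n_b) +
        cbind(100 * sb * cos(el) * cos(azb),
              100 * sb * cos(el) * sin(azb),
              100 * sb * sin(el))
      organs[[length(organs) + 1L]] <- list(pts = rbind(central, branch),
                                            role = "tassel")
    }

    if (spec$include_ear) {
      tt <- 0.55
      az <- (spec$n_leaves * spec$phyllotaxy_deg + 90) * pi / 180
      d <- c(cos(az), sin(az), 0)
      ctr_e <- stem_center(tt) + d * (stem_radius(tt) + 35)
      u <- matrix(rnorm(npo * 3), ncol = 3)
      u <- .row_unit(u) * matrix(runif(npo)^(1 / 3), npo, 3)
      organs[[length(organs) + 1L]] <- list(
        pts = rep(ctr_e, each = npo) +
          cbind(25 * u[, 1], 25 * u[, 2], 60 * u[, 3]),
        role = "ear"
      )
    }

    if (spec$include_pot) {
      # soil surface 40 mm below the first visible stem point, so a generous
      # growth radius at s0 cannot swallow the pot rim
      n_d <- ceiling(npo / 2)
      n_w <- npo - n_d
      disk <- cbind(sqrt(runif(n_d)) * 100, 0, 0)
      phd <- runif(n_d, 0, 2 * pi)
      disk <- cbind(disk[, 1] * cos(phd), disk[, 1] * sin(phd),
                    rep(-40, n_d))
      phw <- runif(n_w, 0, 2 * pi)
      wall <- cbind(100 * cos(phw), 100 * sin(phw), runif(n_w, -160, -40))
      organs[[length(organs) + 1L]] <- list(pts = rbind(disk, wall),
                                            role = "pot")
    }

    roles <- vapply(organs, `[[`, character(1), "role")
    sizes <- vapply(organs, function(o) nrow(o$pts), integer(1))
    coords <- do.call(rbind, lapply(organs, `[[`, "pts"))
    labels <- rep(seq_along(organs), sizes)
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))

    # per-organ highest points (noiseless), skipping stem and pot
    seed_rows <- which(!(roles %in% c("stem", "pot")))
    tip_idx <- vapply(seed_rows, function(i) {
      offsets[i] + which.max(organs[[i]]$pts[, 3])
    }, integer(1))
    tips <- coords[tip_idx, , drop = FALSE]
    if (length(tip_idx) > 1L) {
      sep <- as.matrix(dist(tips))
      diag(sep) <- Inf
      if (min(sep) <= 50) {
        stop(sprintf(paste0("generation error: organ highest points only ",
                            "%.1f mm apart; increase spacing (fewer leaves, ",
                            "taller stem, or less droop)"), min(sep)))
      }
    }

    if (spec$noise_sd_mm > 0) {
      coords <- coords + matrix(rnorm(length(coords), 0, spec$noise_sd_mm),
                                ncol = 3)
    }

    cloud <- labeled_cloud(coords, labels)
    ord <- order(-tips[, 3])
    seeds <- .seed_set(point = tip_idx[ord],
                       id = seed_rows[ord],
                       role = roles[seed_rows][ord],
                       z = tips[ord, 3],
                       min_sep = 50)
    list(cloud = cloud,
         seeds = seeds,
         # endpoints are the lowest/highest stem samples (noiseless), the
         # points an annotator would click; r1 must exceed the worst lateral
         # offset (bow + radius) by enough that consecutive spheres overlap
         # across the whole surface: a "big radius" whose over-capture the
         # median trim removes
         stem = stem_params(
           s0 = organs[[1]]$pts[which.min(organs[[1]]$pts[, 3]), ],
           sn = organs[[1]]$pts[which.max(organs[[1]]$pts[, 3]), ],
           r1 = 2 * spec$stem_radius_bottom_mm + 6),
         roles = roles,
         tips = tips,
         spec = spec)
  })
}

#' Rigidly perturb a cloud
#'
#' Applies a seeded random proper rotation and translation; labels are
#' untouched. Seed 0 is the identity transform by convention.
#'
#' @param cloud a [labeled_cloud()].
#' @param rigid_seed integer seed (0 = identity).
#' @return the transformed cloud, with the applied `rotation` and
#'   `translation` attached as attributes.
#' @export
perturb_cloud <- function(cloud, rigid_seed = 0L) {
  if (rigid_seed == 0L) {
    attr(cloud, "rotation") <- diag(3)
    attr(cloud, "translation") <- c(0, 0, 0)
    return(cloud)
  }
  .with_seed(rigid_seed, {
    qr_d <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_d)
    R <- R %*% diag(sign(diag(qr.R(qr_d))))  # unique Q with positive R diag
    if (det(R) < 0) R[, 3] <- -R[, 3]
    tr <- runif(3, -300, 300)
    cloud$coords <- cloud$coords %*% t(R) + rep(tr, each = nrow(cloud$coords))
    if (!is.null(cloud$normals)) cloud$normals <- cloud$normals %*% t(R)
    attr(cloud, "rotation") <- R
    attr(cloud, "translation") <- tr
    cloud
  })
}
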