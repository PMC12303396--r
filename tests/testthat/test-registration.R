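# Spatial transforms and the four registration strategies.

labeled_points <- function(pts, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("P%02d", seq_len(nrow(pts)))
  montage_points(labels, pts, "custom")
}

test_that("rigid fit recovers identity and constructed motions", {
  set.seed(3)
  pts <- matrix(rnorm(30, sd = 60), 10, 3)
  src <- labeled_points(pts)
  expect_lt(max(abs(rigid_from_correspondences(src, src)$matrix - diag(4))),
            1e-9)
  R <- rotation_about(c(0, 0, 1), pi / 2)
  tgt <- labeled_points(sweep(pts %*% t(R), 2, c(10, 0, 0), "+"))
  tf <- rigid_from_correspondences(src, tgt)
  expect_lt(max(abs(tf$matrix[1:3, 1:3] - R)), 1e-6)
  expect_lt(max(abs(tf$matrix[1:3, 4] - c(10, 0, 0))), 1e-6)
})

test_that("rigid fit matches a brute-force random-restart optimizer", {
  set.seed(12)
  for (rep in 1:3) {
    pts <- matrix(rnorm(30, sd = 50), 10, 3)
    R <- random_rotation(); tr <- rnorm(3, sd = 20)
    noise <- matrix(rnorm(30, sd = 0.5), 10, 3)
    tgt_m <- sweep(pts %*% t(R), 2, tr, "+") + noise
    tf <- rigid_from_correspondences(labeled_points(pts),
                                     labeled_points(tgt_m))
    A <- tf$matrix[1:3, 1:3]
    ours <- sqrt(mean(rowSums((sweep(pts %*% t(A), 2, tf$matrix[1:3, 4],
                                     "+") - tgt_m)^2)))
    # independent brute force: random-restart Nelder-Mead over a rotation
    # vector, translation solved in closed form per candidate
    resid <- function(w) {
      Rw <- rotation_about(w + 1e-12, sqrt(sum(w^2)))
      moved <- pts %*% t(Rw)
      tw <- colMeans(tgt_m) - colMeans(moved)
      sqrt(mean(rowSums((sweep(moved, 2, tw, "+") - tgt_m)^2)))
    }
    best <- Inf
    for (s in 1:12) {
      w0 <- rnorm(3, sd = 1.5)
      o <- optim(w0, resid, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
      best <- min(best, o$value)
    }
    expect_lt(abs(best - ours), 1e-3)
    expect_lte(ours, best + 1e-9)   # closed form is never worse
  }
})

test_that("rigid fit needs 3+ non-collinear shared labels", {
  pts <- matrix(rnorm(30), 10, 3)
  a <- labeled_points(pts[1:2, ], c("A", "B"))
  b <- labeled_points(pts[3:4, ], c("A", "B"))
  expect_error(rigid_from_correspondences(a, b), "too few shared labels")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(rigid_from_correspondences(labeled_points(line),
                                          labeled_points(line)), "collinear")
})

test_that("label order does not matter, only the label keys", {
  set.seed(6)
  pts <- matrix(rnorm(24, sd = 40), 8, 3)
  src <- labeled_points(pts)
  tgt <- labeled_points(sweep(pts, 2, c(4, -2, 9), "+"))
  perm <- sample(8)
  tgt_perm <- tgt[perm, ]
  tf1 <- unscaled_atlas_placement(src, tgt)
  tf2 <- unscaled_atlas_placement(src, tgt_perm)
  expect_equal(tf1$matrix, tf2$matrix, tolerance = 1e-12)
})

test_that("rigid placement of a scaled copy leaves the scale as residual", {
  sph <- sphere_phantom()
  m <- compute_1020(sph$mesh, sph$landmarks)
  bigger <- m
  bigger[, c("x", "y", "z")] <- bigger[, c("x", "y", "z")] * 1.1
  tf <- unscaled_atlas_placement(m, bigger)
  sv <- svd(tf$matrix[1:3, 1:3])$d
  expect_lt(max(abs(sv - 1)), 1e-9)     # no scale leaks into a rigid fit
  expect_gt(attr(tf, "rms"), 1)         # the 10% size mismatch remains
})

test_that("four-point affine maps the defining points exactly", {
  src <- rbind(c(0, 110, 0), c(0, -110, 0), c(-88, 13, -9), c(88, 13, -9))
  expect_lt(max(abs(affine_from_4_points(src, src)$matrix - diag(4))), 1e-9)
  S <- diag(c(1.1, 0.9, 1.05))
  tgt <- src %*% S
  tf <- affine_from_4_points(src, tgt)
  expect_equal(tf$matrix[1:3, 1:3], S, tolerance = 1e-9, ignore_attr = TRUE)
  got <- transform_points(tf, src)
  expect_lt(max(abs(got - tgt)), 1e-9)
})

test_that("coplanar source points are rejected with the tetra volume", {
  src <- rbind(c(0, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(0, -1, 0))
  expect_error(affine_from_4_points(src, src), "coplanar.*volume")
})

test_that("apply_transform respects object structure and isometry", {
  ph <- sphere_phantom()
  ident <- spatial_transform(diag(4), "rigid")
  expect_identical(apply_transform(ident, ph$mesh)$vertices,
                   ph$mesh$vertices)
  set.seed(15)
  R <- random_rotation()
  tf <- scalpmorph:::transform_from_rt(R, c(5, 6, 7))
  m <- matrix(rnorm(30), 10, 3)
  fwd <- apply_transform(tf, m)
  back <- apply_transform(scalpmorph:::transform_invert(tf), fwd)
  expect_lt(max(abs(back - m)), 1e-9)
  expect_equal(as.matrix(dist(fwd)), as.matrix(dist(m)), tolerance = 1e-9)
})

test_that("transforms round trip through their text format", {
  set.seed(9)
  tf <- scalpmorph:::transform_from_rt(random_rotation(), rnorm(3))
  p <- withr::local_tempfile(fileext = ".txt")
  write_transform(tf, p)
  r <- read_transform(p)
  expect_equal(r$matrix, tf$matrix, tolerance = 1e-9)
  expect_identical(r$kind, "rigid")
})

test_that("transform kinds validate their structure", {
  expect_error(spatial_transform(matrix(rnorm(16), 4), "rigid"),
               "bottom row")
  m <- diag(4); m[1:3, 1:3] <- diag(c(2, 1, 1))
  expect_error(spatial_transform(m, "rigid"), "orthonormal")
  expect_s3_class(spatial_transform(m, "anisotropic_similarity"),
                  "spatial_transform")
  m2 <- diag(4); m2[1, 2] <- 0.5   # shear: not R %*% diag(s)
  expect_error(spatial_transform(m2, "anisotropic_similarity"), "factor")
  expect_s3_class(spatial_transform(m2, "affine"), "spatial_transform")
})

test_that("template self-fit is near identity with tiny residual", {
  atlas <- make_head(phantom_spec(shape_perturbation = 0, seed = 0))
  spec <- phantom_spec(shape_perturbation = 0, seed = 0, noise_sigma = 0,
                       hair_thickness = 0)
  cs <- make_cap_scan(atlas, spec, module_geometry())
  fit <- fit_template_to_sample(atlas$scalp_mesh, cs$truth$foot_points,
                                "anisotropic")
  expect_lt(attr(fit, "rms"), 0.1)
  expect_lt(max(abs(fit$matrix - diag(4))), 0.02)
  tr <- attr(fit, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("a known anisotropic similarity is recovered from 68 feet", {
  atlas <- make_head(phantom_spec(shape_perturbation = 0, seed = 0))
  spec <- phantom_spec(shape_perturbation = 0, seed = 0, noise_sigma = 0,
                       hair_thickness = 0)
  cs <- make_cap_scan(atlas, spec, module_geometry())
  ang <- 10 * pi / 180
  R <- rotation_about(c(0, 0, 1), ang)
  m <- diag(4)
  m[1:3, 1:3] <- R %*% diag(c(0.95, 1.05, 1.0))
  m[1:3, 4] <- c(5, -8, 12)
  tf_true <- spatial_transform(m, "anisotropic_similarity")
  target <- transform_points(tf_true, cs$truth$foot_points)
  init <- similarity_from_landmarks(atlas$landmarks,
                                    apply_transform(tf_true, atlas$landmarks))
  fit <- fit_template_to_sample(atlas$scalp_mesh, target, "anisotropic",
                                init = init, max_iter = 200, tol = 1e-6)
  f <- scalpmorph:::polar_rs(fit$matrix[1:3, 1:3])
  expect_lt(max(abs(f$scales / c(0.95, 1.05, 1.0) - 1)), 0.01)
  expect_lt(rotation_angle_deg(f$rotation, R), 1)
})

test_that("rigid-mode fitting leaks no scale", {
  atlas <- make_head(phantom_spec(shape_perturbation = 0, seed = 0))
  spec <- phantom_spec(shape_perturbation = 0, seed = 0, noise_sigma = 0,
                       hair_thickness = 0)
  cs <- make_cap_scan(atlas, spec, module_geometry())
  target <- cs$truth$foot_points * 1.04   # slightly larger head
  fit <- suppressWarnings(
    fit_template_to_sample(atlas$scalp_mesh, target, "none"))
  sv <- svd(fit$matrix[1:3, 1:3])$d
  expect_lt(max(abs(sv - 1)), 1e-9)
  expect_identical(fit$kind, "rigid")
})

test_that("small or clumped samples are rejected", {
  atlas <- make_head(phantom_spec(shape_perturbation = 0, seed = 0))
  expect_error(fit_template_to_sample(atlas$scalp_mesh,
                                      matrix(rnorm(15), 5, 3)),
               "insufficient sample")
  clump <- sweep(matrix(rnorm(45, sd = 2), 15, 3), 2, c(40, 50, 60), "+")
  expect_error(fit_template_to_sample(atlas$scalp_mesh, clump),
               "octant")
})
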