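# Geodesic curves and the 10-20 / modified 10-5 montage construction.

test_that("plane-slice geodesics reproduce great-circle arcs", {
  sph <- sphere_phantom()
  g <- geodesic_curve(sph$mesh, c(0, 100, 0), c(0, -100, 0), c(0, 0, 100))
  expect_equal(g$length, 100 * pi, tolerance = 1)
  # the arc stays on the chosen side
  expect_true(all(g$points[, 3] > -1))
})

test_that("coincident endpoints give a zero-length curve", {
  sph <- sphere_phantom()
  g <- geodesic_curve(sph$mesh, c(0, 100, 0), c(0, 100, 0), c(0, 0, 100))
  expect_equal(g$length, 0)
})

test_that("antipodal points route through the reference side", {
  sph <- sphere_phantom()
  g_up <- geodesic_curve(sph$mesh, c(100, 0, 0), c(-100, 0, 0), c(0, 0, 100))
  g_dn <- geodesic_curve(sph$mesh, c(100, 0, 0), c(-100, 0, 0), c(0, 0, -100))
  expect_equal(g_up$length, 100 * pi, tolerance = 1)
  expect_gt(min(g_up$points[, 3]), -1)
  expect_lt(max(g_dn$points[, 3]), 1)
})

test_that("a plane missing the mesh is reported", {
  sph <- sphere_phantom()
  expect_error(
    geodesic_curve(sph$mesh, c(0, 300, 200), c(0, 290, 210), c(10, 295, 205)),
    "does not intersect|no surface arc")
})

test_that("fractional points interpolate by arc length", {
  sph <- sphere_phantom()
  g <- geodesic_curve(sph$mesh, c(0, 100, 0), c(0, -100, 0), c(0, 0, 100))
  expect_equal(fractional_point(g, 0), g$points[1, ], tolerance = 1e-9)
  expect_equal(fractional_point(g, 1), g$points[nrow(g$points), ],
               tolerance = 1e-9)
  expect_equal(fractional_point(g, 0.5), c(0, 0, 100), tolerance = 1)
  # 10% along: polar angle 18 degrees from the start
  p10 <- fractional_point(g, 0.1)
  expect_equal(p10, 100 * c(0, cos(pi * 0.1), sin(pi * 0.1)), tolerance = 1)
})

test_that("Cz lands at the vertex of the analytic sphere", {
  sph <- sphere_phantom()
  res <- locate_cz(sph$mesh, sph$landmarks)
  expect_equal(res$cz, c(0, 0, 100), tolerance = 1)
  expect_lte(res$iterations, 20L)
})

test_that("Cz iteration converges on ellipsoids with axis ratios 0.7-1.3", {
  for (axes in list(c(70, 100, 85), c(130, 100, 105), c(100, 70, 90))) {
    th <- make_head(phantom_spec(head_semi_axes = axes,
                                 shape_perturbation = 0, seed = 5,
                                 mesh_resolution = 3.4))
    res <- locate_cz(th$scalp_mesh, th$landmarks)
    expect_lte(res$iterations, 20L)
    # Cz is the sagittal and coronal mutual midpoint: re-slice and check
    sag_mid <- fractional_point(res$sagittal, 0.5)
    expect_lt(vnorm(sag_mid - res$cz), 1)
  }
})

test_that("the 10-20 montage matches closed-form positions on the sphere", {
  sph <- sphere_phantom()
  m20 <- compute_1020(sph$mesh, sph$landmarks)
  expect_identical(attr(m20, "montage_id"), "ten20")
  expect_equal(nrow(m20), 21L)
  cells <- scalpmorph:::ten20_cells()
  for (i in seq_len(nrow(cells))) {
    want <- sphere_grid_oracle(cells$level[i], cells$column[i])
    got <- as.numeric(m20[m20$label == cells$label[i], c("x", "y", "z")])
    expect_lt(vnorm(got - want), 1)
  }
})

test_that("the modified 10-5 montage has 289 labels nested over the 10-20", {
  sph <- sphere_phantom()
  m105 <- compute_105_above_ears(sph$mesh, sph$landmarks)
  expect_equal(nrow(m105), 289L)
  expect_false(anyDuplicated(m105$label) > 0)
  m20 <- compute_1020(sph$mesh, sph$landmarks)
  sub <- montage_1020_from_105(m105)
  idx <- match(m20$label, sub$label)
  d <- sqrt(rowSums((as.matrix(m20[, 2:4]) - as.matrix(sub[idx, 2:4]))^2))
  expect_lt(max(d), 0.5)
})

test_that("all 289 positions match the closed-form spherical grid", {
  sph <- sphere_phantom()
  m105 <- compute_105_above_ears(sph$mesh, sph$landmarks)
  g <- ten5_label_grid()
  idx <- match(g$label, m105$label)
  err <- vapply(seq_len(nrow(g)), function(i) {
    vnorm(as.numeric(m105[idx[i], c("x", "y", "z")]) -
          sphere_grid_oracle(g$level[i], g$column[i]))
  }, numeric(1))
  expect_lt(max(err), 1)
})

test_that("montages are equivariant under rigid motion", {
  sph <- sphere_phantom()
  set.seed(19)
  R <- random_rotation(); tr <- c(12, 30, -25)
  tf <- scalpmorph:::transform_from_rt(R, tr)
  m0 <- compute_105_above_ears(sph$mesh, sph$landmarks)
  m1 <- compute_105_above_ears(apply_transform(tf, sph$mesh),
                               apply_transform(tf, sph$landmarks))
  moved <- apply_transform(tf, m0)
  idx <- match(m0$label, m1$label)
  d <- sqrt(rowSums((as.matrix(moved[, 2:4]) - as.matrix(m1[idx, 2:4]))^2))
  expect_lt(max(d), 0.1)
})

test_that("a mirrored head yields the mirrored montage with swapped sides", {
  sph <- sphere_phantom()
  mir <- sph$mesh
  mir$vertices[, 1] <- -mir$vertices[, 1]
  mir$faces <- mir$faces[, c(1, 3, 2)]   # keep outward orientation
  lm <- sph$landmarks                    # preauriculars swap sides
  lm_m <- landmark_set(lm$nasion * c(-1, 1, 1), lm$inion * c(-1, 1, 1),
                       lm$right_preauricular * c(-1, 1, 1),
                       lm$left_preauricular * c(-1, 1, 1))
  m0 <- compute_1020(sph$mesh, sph$landmarks)
  m1 <- compute_1020(mir, lm_m)
  # odd (left) digits pair with the next even (right) digit and vice versa
  swap <- function(lbl) vapply(lbl, function(s) {
    m <- regmatches(s, regexpr("[0-9]", s))
    if (length(m) == 0L) return(s)
    d <- as.integer(m)
    sub("[0-9]", if (d %% 2 == 1L) d + 1L else d - 1L, s)
  }, "", USE.NAMES = FALSE)
  for (i in seq_len(nrow(m0))) {
    partner <- swap(m0$label[i])
    got <- as.numeric(m1[m1$label == partner, c("x", "y", "z")])
    want <- as.numeric(m0[i, c("x", "y", "z")]) * c(-1, 1, 1)
    expect_lt(vnorm(got - want), 0.5)
  }
})

test_that("landmarks far off the surface are rejected", {
  sph <- sphere_phantom()
  bad <- landmark_set(c(0, 150, 0), c(0, -100, 0), c(-100, 0, 0),
                      c(100, 0, 0))
  expect_error(compute_1020(sph$mesh, bad), "off surface")
})

test_that("the shipped label registry equals the generator output", {
  g <- ten5_label_grid()
  path <- system.file("extdata", "ten5_labels.txt", package = "scalpmorph")
  expect_true(nzchar(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tok <- strsplit(lines, " ")
  expect_equal(vapply(tok, `[[`, "", 1L), g$label)
  expect_equal(as.numeric(vapply(tok, `[[`, "", 2L)), g$level)
  expect_equal(as.integer(vapply(tok, `[[`, "", 3L)), g$column)
})

test_that("montage point sets serialise to label x y z text", {
  sph <- sphere_phantom()
  m20 <- compute_1020(sph$mesh, sph$landmarks)
  p <- withr::local_tempfile(fileext = ".txt")
  write_montage(m20, p)
  r <- read_montage(p)
  expect_identical(attr(r, "montage_id"), "ten20")
  expect_equal(r$label, m20$label)
  expect_equal(as.matrix(r[, 2:4]), as.matrix(m20[, 2:4]), tolerance = 1e-5)
})
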