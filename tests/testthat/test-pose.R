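# Module pose recovery: principal axes, inward normals, model alignment,
# foot projection, and the sparse scalp sample.

planar_grid <- function(n = 5, spacing = 2) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  cbind(g$x * spacing, g$y * spacing, 0)
}

test_that("principal axes of a planar grid give the plane normal", {
  ax <- principal_axes(planar_grid())
  expect_equal(abs(ax$axes[, 3]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(crossprod(ax$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("principal axes rotate with the points", {
  set.seed(21)
  # anisotropic grid so all three principal directions are unique
  g <- expand.grid(x = 1:6, y = 1:4)
  pts <- cbind(g$x * 3, g$y * 1.5, 0.2 * g$x * g$y)
  Q <- random_rotation()
  ax0 <- principal_axes(pts)
  ax1 <- principal_axes(pts %*% t(Q))
  for (j in 1:3) {
    d <- abs(sum((Q %*% ax0$axes[, j]) * ax1$axes[, j]))
    expect_equal(d, 1, tolerance = 1e-9)
  }
})

test_that("collinear points are a degenerate cluster", {
  expect_error(principal_axes(cbind(1:3, 1:3, 1:3)), "degenerate")
})

test_that("head centre estimate is the centroid mean and needs 3 clusters", {
  expect_equal(estimate_head_center(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))),
               c(1, 1, 1))
  set.seed(8)
  dirs <- normalize_rows(cbind(rnorm(40), rnorm(40), abs(rnorm(40))))
  expect_lt(vnorm(estimate_head_center(dirs * 100)), 80)
  expect_error(estimate_head_center(rbind(c(0, 0, 0), c(1, 1, 1))),
               "too few clusters")
})

test_that("inward normal points toward the head centre", {
  pts <- sweep(planar_grid(), 2, c(0, 0, 100), "+")
  ax <- principal_axes(pts)
  expect_equal(inward_normal(ax, head_center = c(0, 0, 0)), c(0, 0, -1),
               tolerance = 1e-9)
  expect_equal(inward_normal(ax, head_center = c(0, 0, 200)), c(0, 0, 1),
               tolerance = 1e-9)
  expect_error(inward_normal(ax, head_center = c(500, 0, 100)), "ambiguous")
})

model_cluster <- function(geometry, pose_R = diag(3), pose_t = c(0, 0, 0)) {
  tri <- geometry$triangle_vertices
  # filled triangle patch, matching how a scan samples the fiducial
  pts <- NULL
  n <- 6
  for (i in 0:n) for (j in 0:(n - i)) {
    w <- c(n - i - j, j, i) / n
    pts <- rbind(pts, w[1] * tri[1, ] + w[2] * tri[2, ] + w[3] * tri[3, ])
  }
  fiducial_cluster(seq_len(nrow(pts)), sweep(pts %*% t(pose_R), 2, pose_t, "+"))
}

test_that("identity pose is recovered from a model-generated cluster", {
  geom <- module_geometry()
  cl <- model_cluster(geom)
  pose <- align_module_model(cl, geom, normal = c(0, 0, -1))
  expect_equal(pose$rotation, diag(3), tolerance = 1e-6)
  expect_equal(pose$translation, c(0, 0, 0), tolerance = 1e-6)
  expect_lt(pose$residual_rms, 1e-6)
})

test_that("a known rigid motion of the cluster is recovered", {
  set.seed(31)
  geom <- module_geometry()
  for (rep in 1:4) {
    R <- random_rotation(); tr <- rnorm(3, sd = 40)
    cl <- model_cluster(geom, R, tr)
    inward <- -drop(R %*% c(0, 0, 1))
    pose <- align_module_model(cl, geom, normal = inward)
    expect_lt(rotation_angle_deg(pose$rotation, R), 1e-4)
    expect_lt(vnorm(pose$translation - tr), 1e-4)
  }
})

test_that("equilateral fiducials cannot be oriented", {
  s <- 20
  tri <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  pts <- NULL
  for (i in 0:5) for (j in 0:(5 - i)) {
    w <- c(5 - i - j, j, i) / 5
    pts <- rbind(pts, w[1] * tri[1, ] + w[2] * tri[2, ] + w[3] * tri[3, ])
  }
  cl <- fiducial_cluster(seq_len(nrow(pts)), pts)
  expect_error(align_module_model(cl, module_geometry(), c(0, 0, -1)),
               "ambiguous")
})

test_that("feet project through the pose map", {
  geom <- module_geometry()
  ident <- module_pose(diag(3), c(0, 0, 0))
  expect_equal(project_feet(ident, geom), geom$foot_offsets)
  shifted <- module_pose(diag(3), c(0, 0, 50))
  expect_equal(project_feet(shifted, geom),
               sweep(geom$foot_offsets, 2, c(0, 0, 50), "+"))
})

test_that("module geometry validates the 3-4-5 proportions and feet", {
  geom <- module_geometry()
  expect_equal(geom$hypotenuse, 25)
  expect_true(all(geom$foot_offsets[, 3] == -25))
  expect_error(module_geometry(leg_vertical = -1), "positive")
  expect_error(module_geometry(foot_offsets = cbind(0, 0, -10)), "four feet")
})

test_that("measured legs and plane distance match the build geometry", {
  ph <- noise_free_cap_phantom()
  s <- build_sparse_sample(ph$scan, seed = 1)
  clusters <- attr(s, "clusters")
  poses <- attr(s, "poses")
  geom <- module_geometry()
  for (j in seq_along(clusters)) {
    tri <- measure_fiducial_triangle(clusters[[j]])
    expect_equal(tri$leg_vertical, 20, tolerance = 0.02)
    expect_equal(tri$leg_horizontal, 15, tolerance = 0.02)
    # perpendicular distance from fitted fiducial plane to projected feet
    ax <- principal_axes(clusters[[j]]$points)
    feet <- project_feet(poses[[j]], geom)
    d <- abs(sweep(feet, 2, ax$centroid) %*% ax$axes[, 3])
    expect_equal(as.numeric(d), rep(25, 4), tolerance = 1e-6)
  }
})

test_that("sparse sample covers 17 modules x 4 feet on the default phantom", {
  ph <- default_cap_phantom()
  s <- build_sparse_sample(ph$scan, seed = 1)
  expect_equal(nrow(s$points), 68L)
  expect_equal(length(unique(s$module_ids)), 17L)
  expect_equal(nrow(s$points), 4L * length(unique(s$module_ids)))
})

test_that("foot recovery error stays within the noise budget", {
  for (case in list(list(ph = noise_free_cap_phantom(), bound = 0.5),
                    list(ph = default_cap_phantom(), bound = 1.5))) {
    s <- build_sparse_sample(case$ph$scan, seed = 1)
    truth_feet <- case$ph$truth$foot_points
    nn <- apply(s$points, 1, function(p)
      min(sqrt(colSums((t(truth_feet) - p)^2))))
    expect_lt(mean(nn), case$bound)
  }
})

test_that("recovered inward normals face the scalp on all modules", {
  ph <- noise_free_cap_phantom()
  s <- build_sparse_sample(ph$scan, seed = 1)
  clusters <- attr(s, "clusters")
  hc <- attr(s, "head_center")
  for (cl in clusters) {
    ax <- principal_axes(cl$points)
    n <- inward_normal(ax, head_center = hc)
    # the true inward direction at the module is minus its placement direction
    expect_gt(sum(n * (hc - cl$centroid)), 0)
    expect_lt(sum(n * cl$centroid / vnorm(cl$centroid)), 0)
  }
})

test_that("pose pipeline is equivariant under a global rigid motion", {
  ph <- noise_free_cap_phantom()
  set.seed(77)
  R <- random_rotation(); tr <- c(25, -40, 10)
  moved <- ph$scan
  moved$vertices <- sweep(moved$vertices %*% t(R), 2, tr, "+")
  s0 <- build_sparse_sample(ph$scan, seed = 1)
  s1 <- build_sparse_sample(moved, seed = 1)
  # match feet by nearest neighbour after applying the motion
  mapped <- sweep(s0$points %*% t(R), 2, tr, "+")
  nn <- apply(mapped, 1, function(p) min(sqrt(colSums((t(s1$points) - p)^2))))
  expect_lt(max(nn), 1e-6)
})

test_that("occluded modules are skipped with warnings, the rest survive", {
  spec <- phantom_spec(seed = 2)
  truth <- make_head(spec)
  cs <- make_cap_scan(truth, spec, module_geometry())
  # occlude two modules: repaint their fiducials hair-colored
  idx <- filter_fiducial_vertices(cs$scan)
  cl <- cluster_fiducials(cs$scan$vertices[idx, ], k = 17, seed = 1,
                          member_indices = idx)
  hide <- unlist(lapply(cl[1:2], `[[`, "member_indices"))
  occluded <- cs$scan
  occluded$colors[hide, ] <- matrix(c(0.3, 0.25, 0.2), length(hide), 3,
                                    byrow = TRUE)
  w <- capture_warnings(s <- build_sparse_sample(occluded, seed = 1))
  expect_gte(sum(grepl("skipped", w)), 2L)
  expect_gte(length(unique(s$module_ids)), 13L)
  expect_equal(nrow(s$points), 4L * length(unique(s$module_ids)))
  # surviving feet are still accurate
  nn <- apply(s$points, 1, function(p)
    min(sqrt(colSums((t(cs$truth$foot_points) - p)^2))))
  expect_lt(mean(nn), 1.5)
})

test_that("a scan with no fiducial vertices fails with a clear error", {
  ph <- default_cap_phantom()
  gray <- ph$scan
  gray$colors <- matrix(0.4, nrow(gray$colors), 3)
  expect_error(build_sparse_sample(gray, seed = 1), "color filtering")
})
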