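# Independent oracles and shared fixtures for the test suite. Oracles are
# written from first principles (hexcone HSV, great-circle trigonometry,
# brute-force optimisation) and never call the implementation paths they
# check.

# ---- hexcone HSV oracle ----------------------------------------------------

# Straight transcription of the hexcone model: value = max channel,
# saturation = chroma / value, hue in [0, 1) from the dominant channel.
oracle_hsv <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3L)
  t(apply(rgb, 1, function(p) {
    mx <- max(p); mn <- min(p); c0 <- mx - mn
    s <- if (mx > 0) c0 / mx else 0
    h <- if (c0 == 0) 0
    else if (mx == p[1]) ((p[2] - p[3]) / c0) %% 6
    else if (mx == p[2]) (p[3] - p[1]) / c0 + 2
    else (p[1] - p[2]) / c0 + 4
    c(h = h / 6, s = s, v = mx)
  }))
}

oracle_filter_pass <- function(rgb, red_min = 0.5, sat_min = 0.7,
                               hue_max = 0.1) {
  hsv <- oracle_hsv(rgb)
  rgb <- matrix(rgb, ncol = 3L)
  rgb[, 1] >= red_min & hsv[, "s"] >= sat_min &
    (hsv[, "h"] <= hue_max | hsv[, "h"] >= 1 - hue_max)
}

# ---- rotations -------------------------------------------------------------

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  rotation_about(stats::rnorm(3), stats::runif(1, 0, pi))
}

rotation_angle_deg <- function(R1, R2 = diag(3)) {
  acos(min(1, max(-1, (sum(diag(R1 %*% t(R2))) - 1) / 2))) * 180 / pi
}

# ---- closed-form montage positions on a sphere -----------------------------

# Analytic grid positions for a sphere of radius R with landmarks at the
# axis poles: circles from plane/sphere intersection, arc fractions by
# uniform angle (independent of the mesh-based construction).
sphere_grid_oracle <- function(f, k, R = 100) {
  midline <- function(f) c(0, R * cos(pi * f), R * sin(pi * f))
  if (k == 8) return(midline(f))
  mirror <- k > 8
  if (mirror) k <- 16 - k
  zr <- R * sin(0.1 * pi)
  rr <- R * cos(0.1 * pi)
  a <- pi / 2 + pi * f
  Pl <- c(rr * cos(a), rr * sin(a), zr)
  Pr <- Pl * c(-1, 1, 1)
  M <- midline(f)
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n <- cr(Pr - Pl, M - Pl); n <- n / sqrt(sum(n^2))
  c0 <- sum(n * Pl) * n                   # circle centre
  rho <- sqrt(R^2 - sum(c0^2))            # circle radius
  u1 <- (Pl - c0) / rho; u2 <- (M - c0) / rho
  phi <- acos(sum(u1 * u2))
  t <- k / 8
  p <- c0 + rho * (sin((1 - t) * phi) * u1 + sin(t * phi) * u2) / sin(phi)
  if (mirror) p * c(-1, 1, 1) else p
}

# ---- shared fixtures -------------------------------------------------------

sphere_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      th <- make_head(phantom_spec(head_semi_axes = c(100, 100, 100),
                                   shape_perturbation = 0, seed = 7,
                                   mesh_resolution = 5))
      lm <- landmark_set(c(0, 100, 0), c(0, -100, 0),
                         c(-100, 0, 0), c(100, 0, 0))
      cache <<- list(mesh = th$scalp_mesh, landmarks = lm)
    }
    cache
  }
})

default_cap_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(seed = 1)
      truth <- make_head(spec)
      cs <- make_cap_scan(truth, spec, module_geometry())
      cache <<- list(spec = spec, truth = cs$truth, scan = cs$scan)
    }
    cache
  }
})

noise_free_cap_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(seed = 1, noise_sigma = 0)
      truth <- make_head(spec)
      cs <- make_cap_scan(truth, spec, module_geometry())
      cache <<- list(spec = spec, truth = cs$truth, scan = cs$scan)
    }
    cache
  }
})

# smallest colored mesh with faces: a tetrahedron
tetra_mesh <- function(colors = c(1, 0, 0)) {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  colored_mesh(v, f, colors)
}
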