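# Synthetic phantom generator: perturbed-ellipsoid head surfaces with known
# ground truth, and simulated cap scans emulating what the 3D scanner sees —
# the hair envelope (the scalp offset outward by the hair thickness), black
# module bodies, and red fiducial triangles on the module tops, with the
# module feet combed through the hair onto the true scalp.

#' Phantom specification
#'
#' Study conditions for one synthetic head and cap scan. Defaults model an
#' adult head (ellipsoid semi-axes 90/110/95 mm, smooth seeded shape bumps of
#' 3 mm), a typical hair envelope of 8 mm, the 17-module cap, and scanner
#' vertex noise of 0.3 mm.
#'
#' @param head_semi_axes ellipsoid semi-axes (x, y, z) in mm.
#' @param shape_perturbation peak amplitude of smooth seeded radial bumps, mm.
#' @param hair_thickness outward hair-envelope offset, mm.
#' @param n_modules number of cap modules.
#' @param module_layout optional n x 3 matrix of unit placement directions on
#'   the upper scalp; defaults to a spherical Fibonacci layout above ear
#'   level.
#' @param noise_sigma scanner vertex noise (per-coordinate standard
#'   deviation), mm.
#' @param seed integer seed; all phantom randomness derives from it.
#' @param mesh_resolution target mesh edge length, mm.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_semi_axes = c(90, 110, 95),
                         shape_perturbation = 3, hair_thickness = 8,
                         n_modules = 17L, module_layout = NULL,
                         noise_sigma = 0.3, seed = 1L,
                         mesh_resolution = 4) {
  stopifnot(length(head_semi_axes) == 3L, all(head_semi_axes > 0),
            shape_perturbation >= 0, hair_thickness >= 0, n_modules >= 1L,
            noise_sigma >= 0, mesh_resolution > 0)
  if (!is.null(module_layout)) {
    module_layout <- normalize_rows(matrix(as.numeric(module_layout),
                                           ncol = 3L))
    if (any(module_layout[, 3] <= 0))
      stop("module placements must lie above the ear-level plane",
           call. = FALSE)
  }
  structure(list(head_semi_axes = as.numeric(head_semi_axes),
                 shape_perturbation = shape_perturbation,
                 hair_thickness = hair_thickness,
                 n_modules = as.integer(n_modules),
                 module_layout = module_layout,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 mesh_resolution = mesh_resolution),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

## ---- unit icosphere ------------------------------------------------------

icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(ek)
    mididx <- nrow(v) + match(ek, uk)
    ue <- e[match(uk, ek), , drop = FALSE]
    mids <- normalize_rows((v[ue[, 1], , drop = FALSE] +
                            v[ue[, 2], , drop = FALSE]) / 2)
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

## ---- head generation ------------------------------------------------------

# Smooth seeded bump field on the direction sphere: a sum of spherical
# Gaussians, rescaled so the peak magnitude equals `amplitude`.
make_bump_field <- function(amplitude, n_bumps = 12L) {
  if (amplitude <= 0) return(function(dirs) rep(0, nrow(dirs)))
  u <- normalize_rows(matrix(stats::rnorm(3L * n_bumps), n_bumps, 3L))
  w <- stats::runif(n_bumps, 0.25, 0.60)       # angular widths, rad
  a <- stats::runif(n_bumps, -1, 1)
  raw <- function(dirs) {
    ang <- acos(pmin(pmax(dirs %*% t(u), -1), 1))
    drop(exp(-ang^2 / (2 * matrix(w^2, nrow(dirs), n_bumps, byrow = TRUE))) %*% a)
  }
  probe <- normalize_rows(matrix(stats::rnorm(3000), 1000L, 3L))
  peak <- max(abs(raw(probe)))
  scale <- amplitude / max(peak, 1e-9)
  function(dirs) raw(dirs) * scale
}

#' Generate a synthetic head (scalp surface and landmarks)
#'
#' Builds a watertight perturbed-ellipsoid scalp mesh at the requested
#' resolution and places the four cranial landmarks deterministically from
#' the seed: nasion at the anterior pole, inion at the posterior pole, and
#' the preauricular points at the lateral extremes (slightly anterior and
#' inferior, as on a real head, so that the four landmarks are not coplanar).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: list with `scalp_mesh`
#'   ([colored_mesh()]), `landmarks` ([landmark_set()]), `radial` (the
#'   analytic radius function over unit directions), and `spec`. Module
#'   ground truth is filled in by [make_cap_scan()].
#' @export
make_head <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- spec$head_semi_axes
  if (spec$mesh_resolution > 0.05 * min(ax))
    stop(sprintf(paste0("resolution too coarse: %.1f mm exceeds 5%% of the ",
                        "smallest semi-axis (%.1f mm)"),
                 spec$mesh_resolution, 0.05 * min(ax)), call. = FALSE)
  with_seed(spec$seed, {
    bump <- make_bump_field(spec$shape_perturbation)
    r_ell <- function(dirs)
      1 / sqrt((dirs[, 1] / ax[1])^2 + (dirs[, 2] / ax[2])^2 +
               (dirs[, 3] / ax[3])^2)
    radial <- function(dirs) {
      dirs <- matrix(as.numeric(dirs), ncol = 3L)
      r_ell(dirs) + bump(dirs)
    }
    rbar <- mean(ax)
    level <- max(1L, ceiling(log2(1.05146 * rbar / spec$mesh_resolution)))
    ico <- icosphere(level)
    verts <- ico$vertices * radial(ico$vertices)
    mesh <- colored_mesh(verts, ico$faces, c(0.85, 0.66, 0.55))
    lm_dirs <- rbind(nasion = c(0, 1, 0), inion = c(0, -1, 0),
                     left_preauricular = unitize(c(-1, 0.15, -0.10)),
                     right_preauricular = unitize(c(1, 0.15, -0.10)))
    lm_pts <- lm_dirs * radial(lm_dirs)
    landmarks <- landmark_set(lm_pts[1, ], lm_pts[2, ], lm_pts[3, ],
                              lm_pts[4, ])
    structure(list(scalp_mesh = mesh, landmarks = landmarks,
                   radial = radial, spec = spec,
                   module_poses = NULL, foot_points = NULL,
                   hair_mesh = NULL, montage_truth = NULL),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> seed %d, %d scalp vertices%s\n",
              x$spec$seed, nrow(x$scalp_mesh$vertices),
              if (is.null(x$module_poses)) ""
              else sprintf(", %d posed modules", length(x$module_poses))))
  invisible(x)
}

# Quasi-uniform module placement directions above ear level (spherical
# Fibonacci on the superior cap).
default_module_layout <- function(n, z_range = c(0.40, 0.95)) {
  i <- seq_len(n)
  z <- z_range[1] + (z_range[2] - z_range[1]) * (i - 0.5) / n
  phi <- i * 2.39996322972865
  cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
}

# Outward surface normal of the analytic phantom surface at direction d
# (central differences over the direction sphere).
phantom_surface_normal <- function(radial, d, eps = 1e-3) {
  d <- unitize(d)
  t1 <- if (abs(d[3]) < 0.9) unitize(cross3(d, c(0, 0, 1)))
        else unitize(cross3(d, c(0, 1, 0)))
  t2 <- cross3(d, t1)
  sp <- function(dir) { dir <- unitize(dir); dir * radial(rbind(dir)) }
  du <- sp(d + eps * t1) - sp(d - eps * t1)
  dv <- sp(d + eps * t2) - sp(d - eps * t2)
  n <- unitize(cross3(du, dv))
  if (sum(n * d) < 0) -n else n
}

# Subdivided triangle patch (barycentric refinement, exact corner vertices).
subdivide_triangle <- function(p1, p2, p3, n = 4L) {
  verts <- NULL
  idx <- matrix(0L, n + 1L, n + 1L)
  vi <- 0L
  for (i in 0:n) for (j in 0:(n - i)) {
    vi <- vi + 1L
    idx[i + 1L, j + 1L] <- vi
    w <- c(n - i - j, j, i) / n
    verts <- rbind(verts, w[1] * p1 + w[2] * p2 + w[3] * p3)
  }
  faces <- NULL
  for (i in 0:(n - 1L)) for (j in 0:(n - 1L - i)) {
    a <- idx[i + 1L, j + 1L]; b <- idx[i + 1L, j + 2L]
    c1 <- idx[i + 2L, j + 1L]
    faces <- rbind(faces, c(a, b, c1))
    if (j < n - 1L - i)
      faces <- rbind(faces, c(b, idx[i + 2L, j + 2L], c1))
  }
  list(vertices = verts, faces = faces)
}

# Rectangular grid patch in the z = 0 plane.
grid_patch <- function(xr, yr, nx = 4L, ny = 4L) {
  xs <- seq(xr[1], xr[2], length.out = nx + 1L)
  ys <- seq(yr[1], yr[2], length.out = ny + 1L)
  verts <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L), 0)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  faces <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    faces <- rbind(faces,
                   c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                   c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  }
  list(vertices = verts, faces = faces)
}

# Build one module's scan-visible mesh in the module frame: black top plate
# with a short skirt, red fiducial triangle slightly proud of the plate. The
# feet are not rendered (the scanner cannot see them under the hair).
module_scan_mesh <- function(geometry) {
  tri <- geometry$triangle_vertices
  g <- colMeans(tri)
  plate <- grid_patch(g[1] + c(-14, 14), g[2] + c(-14, 14))
  black <- c(0.07, 0.07, 0.07)
  plate_mesh <- colored_mesh(plate$vertices, plate$faces, black)
  corners <- rbind(c(g[1] - 14, g[2] - 14, 0), c(g[1] + 14, g[2] - 14, 0),
                   c(g[1] + 14, g[2] + 14, 0), c(g[1] - 14, g[2] + 14, 0))
  skirt_depth <- 12
  sk_v <- rbind(corners, sweep(corners, 2, c(0, 0, skirt_depth)))
  sk_f <- NULL
  for (i in 1:4) {
    j <- i %% 4L + 1L
    sk_f <- rbind(sk_f, c(i, j, j + 4L), c(i, j + 4L, i + 4L))
  }
  skirt_mesh <- colored_mesh(sk_v, sk_f, black)
  # the fiducial is printed on the module top: same plane as the plate
  tp <- subdivide_triangle(tri[1, ], tri[2, ], tri[3, ], n = 4L)
  tri_mesh <- colored_mesh(tp$vertices, tp$faces, c(0.85, 0.06, 0.06))
  list(mesh = merge_meshes(plate_mesh, skirt_mesh, tri_mesh),
       n_fiducial_vertices = nrow(tp$vertices),
       fiducial_offset = nrow(plate_mesh$vertices) + nrow(sk_v))
}

rot_axis <- function(axis, angle) {
  axis <- unitize(axis)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Seat one module on the analytic surface: starting from the outward normal
# pose at placement direction `d`, adjust height offset and two tilts so the
# four foot tips rest on the scalp (least-squares on the radial residuals).
seat_module <- function(radial, d, geometry) {
  d <- unitize(d)
  p0 <- d * radial(rbind(d))
  nrm <- phantom_surface_normal(radial, d)
  ax <- if (abs(nrm[3]) < 0.9) unitize(cross3(c(0, 0, 1), nrm))
        else unitize(cross3(c(0, 1, 0), nrm))
  ay <- cross3(nrm, ax)
  R0 <- cbind(ax, ay, nrm)
  g <- colMeans(geometry$triangle_vertices)
  feet_local <- geometry$foot_offsets
  h <- geometry$height
  fw <- function(par) {
    R <- R0 %*% rot_axis(c(1, 0, 0), par[2]) %*% rot_axis(c(0, 1, 0), par[3])
    tr <- p0 + (h + par[1]) * nrm - drop(R %*% c(g[1], g[2], 0))
    list(R = R, tr = tr,
         feet = sweep(feet_local %*% t(R), 2, tr, "+"))
  }
  objective <- function(par) {
    f <- fw(par)$feet
    dirs <- normalize_rows(f)
    sum((row_norms(f) - radial(dirs))^2)
  }
  fit <- stats::optim(c(0, 0, 0), objective, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  final <- fw(fit$par)
  pose <- module_pose(final$R, final$tr)
  dirs <- normalize_rows(final$feet)
  feet_true <- dirs * radial(dirs)
  list(pose = pose, feet = final$feet, feet_on_scalp = feet_true,
       seat_residual = sqrt(fit$value / 4))
}

#' Simulate a cap scan
#'
#' Assembles the scanner's view of a capped head: the hair envelope (scalp
#' offset outward along vertex normals by the hair thickness, hair-colored),
#' one black module body per placement with its red fiducial triangle on top,
#' seated so the module feet rest on the true scalp, plus seeded Gaussian
#' vertex noise. Ground-truth module poses and foot points are recorded in
#' the returned copy of `truth`.
#'
#' @param truth a [make_head()] result.
#' @param spec the [phantom_spec()] used for the head.
#' @param geometry a [module_geometry()].
#' @return list with `scan` (the cap-scan [colored_mesh()]) and `truth` (the
#'   input truth with `module_poses`, `foot_points`, `module_layout` and
#'   `hair_mesh` filled in; `hair_mesh` is the matching bare scan without the
#'   cap, with its own noise draw).
#' @export
make_cap_scan <- function(truth, spec = truth$spec,
                          geometry = module_geometry()) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(geometry, "module_geometry"))
  layout <- spec$module_layout
  if (is.null(layout)) layout <- default_module_layout(spec$n_modules)
  if (nrow(layout) != spec$n_modules)
    stop("module layout size disagrees with n_modules", call. = FALSE)
  centers <- layout * drop(truth$radial(layout))
  if (spec$n_modules > 1L) {
    dmin <- min(stats::dist(centers))
    if (dmin < 34)
      stop(sprintf("modules overlap: minimum centre separation %.1f mm", dmin),
           call. = FALSE)
  }
  with_seed(spec$seed + 1000L, {
    scalp <- truth$scalp_mesh
    vn <- vertex_normals(scalp)
    hair_col_base <- c(0.32, 0.24, 0.16)
    jitter <- matrix(stats::runif(3L * nrow(scalp$vertices), -0.04, 0.04),
                     ncol = 3L)
    hair_cols <- pmin(pmax(sweep(jitter, 2, hair_col_base, "+"), 0), 1)
    hair_verts <- scalp$vertices + spec$hair_thickness * vn
    hair <- colored_mesh(hair_verts, scalp$faces, hair_cols)

    mm <- module_scan_mesh(geometry)
    poses <- vector("list", spec$n_modules)
    feet_true <- NULL
    parts <- list(hair)
    for (j in seq_len(spec$n_modules)) {
      seat <- seat_module(truth$radial, layout[j, ], geometry)
      poses[[j]] <- seat$pose
      feet_true <- rbind(feet_true, seat$feet_on_scalp)
      mj <- mm$mesh
      mj$vertices <- pose_apply(seat$pose, mj$vertices)
      parts[[length(parts) + 1L]] <- mj
    }
    scan <- do.call(merge_meshes, parts)
    if (spec$noise_sigma > 0)
      scan$vertices <- scan$vertices +
        matrix(stats::rnorm(length(scan$vertices), 0, spec$noise_sigma),
               ncol = 3L)
    hair_only <- hair
    if (spec$noise_sigma > 0)
      hair_only$vertices <- hair_only$vertices +
        matrix(stats::rnorm(length(hair_only$vertices), 0, spec$noise_sigma),
               ncol = 3L)
    truth$module_poses <- poses
    truth$foot_points <- feet_true
    truth$module_layout <- layout
    truth$hair_mesh <- hair_only
    attr(scan, "n_fiducial_vertices_per_module") <- mm$n_fiducial_vertices
    list(scan = scan, truth = truth)
  })
}

#' Comparison-method variants of a cap scan
#'
#' `"without_legs"` returns the scan unchanged but carries a zero-height
#' module geometry (feet on the fiducial plane), emulating scalp estimation
#' that does not account for the module leg length. `"without_cap"` returns
#' the bare scan: the hair envelope alone, with no modules.
#'
#' @param scan the cap scan from [make_cap_scan()].
#' @param truth the matching `phantom_truth`.
#' @param geometry the [module_geometry()] used for the scan.
#' @param variant `"without_legs"` or `"without_cap"`.
#' @return a [colored_mesh()]; for `"without_legs"` the attribute `geometry`
#'   holds the zero-height [module_geometry()] to use downstream.
#' @export
strip_legs_variant <- function(scan, truth, geometry = module_geometry(),
                               variant = c("without_legs", "without_cap")) {
  variant <- match.arg(variant)
  if (variant == "without_cap") {
    if (is.null(truth$hair_mesh))
      stop("truth carries no bare scan; run make_cap_scan first", call. = FALSE)
    out <- truth$hair_mesh
    attr(out, "variant") <- "without_cap"
    return(out)
  }
  g0 <- module_geometry(geometry$leg_vertical, geometry$leg_horizontal,
                        height = 0,
                        foot_offsets = cbind(geometry$foot_offsets[, 1:2], 0))
  attr(scan, "variant") <- "without_legs"
  attr(scan, "geometry") <- g0
  scan
}
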