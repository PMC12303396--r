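# Module pose recovery: from a fiducial cluster to the module's 6-DOF pose
# and the projected foot points on the scalp.
#
# Module local frame: the fiducial plane is z = 0 with the right-angle vertex
# of the 3-4-5 triangle at the origin, the short (horizontal) leg along +x,
# the long (vertical) leg along +y, and +z pointing away from the head. The
# four feet sit at z = -height and comb through the hair to touch the scalp.

#' Photogrammetric module geometry
#'
#' Physical dimensions of a cap module: the right-triangle fiducial printed on
#' its top (legs 20 mm and 15 mm by default, hypotenuse 25 mm, the 3-4-5
#' proportion that makes orientation recoverable from leg-length asymmetry),
#' the module height from fiducial plane to foot tips (25 mm), and the foot
#' positions in the module frame (by default the corners of a 14 x 14 mm
#' square centred under the triangle centroid).
#'
#' @param leg_vertical long leg of the fiducial triangle, mm (default 20).
#' @param leg_horizontal short leg, mm (default 15).
#' @param height fiducial plane to foot tips, mm (default 25).
#' @param foot_offsets 4 x 3 matrix of foot positions in the module frame;
#'   all rows must have z = -height.
#' @return object of class `module_geometry` with the above fields plus
#'   `triangle_vertices` (right angle at the origin, then the horizontal and
#'   vertical leg tips).
#' @export
module_geometry <- function(leg_vertical = 20, leg_horizontal = 15,
                            height = 25, foot_offsets = NULL) {
  if (leg_vertical <= 0 || leg_horizontal <= 0)
    stop("leg lengths must be positive", call. = FALSE)
  if (height < 0) stop("`height` must be >= 0", call. = FALSE)
  tri <- rbind(corner = c(0, 0, 0),
               horizontal = c(leg_horizontal, 0, 0),
               vertical = c(0, leg_vertical, 0))
  if (is.null(foot_offsets)) {
    ctr <- colMeans(tri)[1:2]
    foot_offsets <- cbind(ctr[1] + c(-7, 7, 7, -7),
                          ctr[2] + c(-7, -7, 7, 7),
                          -height)
  }
  foot_offsets <- matrix(as.numeric(foot_offsets), ncol = 3L)
  if (nrow(foot_offsets) != 4L)
    stop("`foot_offsets` must hold four feet", call. = FALSE)
  if (any(abs(foot_offsets[, 3] + height) > 1e-9))
    stop("all foot offsets must have z = -height", call. = FALSE)
  structure(list(leg_vertical = leg_vertical, leg_horizontal = leg_horizontal,
                 hypotenuse = sqrt(leg_vertical^2 + leg_horizontal^2),
                 height = height, foot_offsets = foot_offsets,
                 triangle_vertices = tri),
            class = "module_geometry")
}

#' Rigid module pose
#'
#' Maps module-frame points `p` into the scan frame as `R p + t`.
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 vector, mm.
#' @param residual_rms RMS distance between the posed model triangle vertices
#'   and the observed triangle corners (diagnostic, mm).
#' @return object of class `module_pose`.
#' @export
module_pose <- function(rotation, translation, residual_rms = NA_real_) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("`rotation` must be proper orthonormal (det +1)", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 residual_rms = residual_rms),
            class = "module_pose")
}

pose_apply <- function(pose, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  sweep(points %*% t(pose$rotation), 2, pose$translation, "+")
}

#' Principal axes of a point cluster
#'
#' PCA of the member coordinates: returns the centroid and three orthonormal
#' axes ordered by decreasing variance. The third axis is the normal of the
#' best-fit plane.
#'
#' @param points n x 3 matrix (n >= 3, not collinear).
#' @return list with `centroid` (length 3) and `axes` (3 x 3, axes in
#'   columns).
#' @export
principal_axes <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 3L)
    stop("degenerate cluster: need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  s <- svd(x)
  # collinear/coincident clusters have (almost) no second direction
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate cluster: points are collinear or coincident",
         call. = FALSE)
  list(centroid = ctr, axes = s$v)
}

#' Rough head-centre estimate from cluster centroids
#'
#' The mean of the module cluster centroids. The modules cover the upper
#' scalp, so the mean falls inside the head; it is used only to give each
#' module plane a sign (which side faces the head).
#'
#' @param cluster_centroids matrix of centroids (one per row) or list of
#'   length-3 vectors.
#' @return length-3 vector, mm.
#' @export
estimate_head_center <- function(cluster_centroids) {
  if (is.list(cluster_centroids))
    cluster_centroids <- do.call(rbind, cluster_centroids)
  cluster_centroids <- matrix(as.numeric(cluster_centroids), ncol = 3L)
  if (nrow(cluster_centroids) < 3L)
    stop("too few clusters: need at least 3 centroids", call. = FALSE)
  colMeans(cluster_centroids)
}

#' Inward plane normal
#'
#' Returns the cluster's third principal axis with the sign chosen so that it
#' points toward the head centre.
#'
#' @param axes result of [principal_axes()].
#' @param centroid cluster centroid (defaults to `axes$centroid`).
#' @param head_center head-centre estimate, see [estimate_head_center()].
#' @return unit length-3 vector.
#' @export
inward_normal <- function(axes, centroid = axes$centroid, head_center) {
  n <- axes$axes[, 3]
  s <- sum(n * (head_center - centroid))
  if (abs(s) < 1e-12)
    stop("ambiguous normal: head centre lies in the cluster plane",
         call. = FALSE)
  if (s > 0) n else -n
}

# Squared distances from a set of points to one triangle (a, b, c):
# vectorized closest-point-on-triangle over the query points.
dist2_points_to_triangle <- function(P, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- sweep(P, 2, a)
  d1 <- drop(ap %*% ab); d2 <- drop(ap %*% ac)
  bp <- sweep(P, 2, b)
  d3 <- drop(bp %*% ab); d4 <- drop(bp %*% ac)
  cp <- sweep(P, 2, c)
  d5 <- drop(cp %*% ab); d6 <- drop(cp %*% ac)
  n <- nrow(P)
  q <- matrix(NA_real_, n, 3L)
  done <- rep(FALSE, n)
  fill <- function(idx, val) {
    if (any(idx)) q[idx, ] <<- val[idx, , drop = FALSE]
    done <<- done | idx
  }
  rep_row <- function(v) matrix(v, n, 3L, byrow = TRUE)
  fill(!done & d1 <= 0 & d2 <= 0, rep_row(a))
  fill(!done & d3 >= 0 & d4 <= d3, rep_row(b))
  fill(!done & d6 >= 0 & d5 <= d6, rep_row(c))
  vc <- d1 * d4 - d3 * d2
  w <- d1 / pmax(d1 - d3, 1e-300)
  fill(!done & vc <= 0 & d1 >= 0 & d3 <= 0, rep_row(a) + outer(w, ab))
  vb <- d5 * d2 - d1 * d6
  w <- d2 / pmax(d2 - d6, 1e-300)
  fill(!done & vb <= 0 & d2 >= 0 & d6 <= 0, rep_row(a) + outer(w, ac))
  va <- d3 * d6 - d5 * d4
  w <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  fill(!done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
       rep_row(b) + outer(w, c - b))
  if (any(!done)) {
    denom <- 1 / (va + vb + vc)
    v <- vb * denom; w2 <- vc * denom
    q[!done, ] <- (rep_row(a) + outer(v, ab) + outer(w2, ac))[!done, , drop = FALSE]
  }
  rowSums((P - q)^2)
}

# Small-angle rotation from a rotation vector (Rodrigues).
rotation_from_vector <- function(w) {
  th <- sqrt(sum(w * w))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# The three corners of the observed fiducial triangle, from the (possibly
# noisy) filled patch of filtered vertices: project onto the PCA plane, then
# take the extremal hull points (farthest from centre, farthest from the
# first, largest triangle area).
triangle_corners <- function(points, axes = principal_axes(points)) {
  x <- sweep(points, 2, axes$centroid)
  uv <- x %*% axes$axes[, 1:2]
  d0 <- rowSums(uv^2)
  i1 <- which.max(d0)
  i2 <- which.max(rowSums(sweep(uv, 2, uv[i1, ])^2))
  e <- uv[i2, ] - uv[i1, ]
  area2 <- abs(e[1] * (uv[, 2] - uv[i1, 2]) - e[2] * (uv[, 1] - uv[i1, 1]))
  i3 <- which.max(area2)
  idx <- c(i1, i2, i3)
  if (length(unique(idx)) < 3L)
    stop("degenerate cluster: could not find three distinct corners",
         call. = FALSE)
  points[idx, , drop = FALSE]
}

#' Measure the observed fiducial triangle
#'
#' Finds the three corners of a fiducial cluster and identifies the
#' right-angle vertex and the two legs by length: the hypotenuse is the
#' longest pairwise distance, and its opposite vertex is the right-angle
#' corner.
#'
#' @param cluster a [fiducial_cluster()] or an n x 3 point matrix.
#' @return list with `corner` (right-angle vertex), `vertical_tip`,
#'   `horizontal_tip`, `leg_vertical`, `leg_horizontal`, `hypotenuse`
#'   (measured lengths, mm).
#' @export
measure_fiducial_triangle <- function(cluster) {
  points <- if (inherits(cluster, "fiducial_cluster")) cluster$points
            else matrix(as.numeric(cluster), ncol = 3L)
  corners <- triangle_corners(points)
  d <- as.matrix(stats::dist(corners))
  hyp_pair <- which(d == max(d), arr.ind = TRUE)[1, ]
  ci <- setdiff(1:3, hyp_pair)
  tips <- corners[hyp_pair, , drop = FALSE]
  legs <- c(d[ci, hyp_pair[1]], d[ci, hyp_pair[2]])
  ord <- order(-legs)   # first: long (vertical) leg
  list(corner = corners[ci, ],
       vertical_tip = tips[ord[1], ],
       horizontal_tip = tips[ord[2], ],
       leg_vertical = legs[ord[1]],
       leg_horizontal = legs[ord[2]],
       hypotenuse = max(d))
}

#' Align the module model to an observed fiducial cluster
#'
#' Recovers the module's rigid pose from its fiducial cluster. The observed
#' triangle corners are matched to the model triangle by leg length (the
#' 20 mm vs 15 mm asymmetry resolves the in-plane orientation including the
#' 180-degree ambiguity), the pose is the least-squares rigid fit over the
#' three corner correspondences, and the result is checked against the inward
#' plane normal.
#'
#' @param cluster a [fiducial_cluster()].
#' @param geometry a [module_geometry()].
#' @param normal inward unit normal from [inward_normal()].
#' @param ratio_tol ambiguity guard: error when the observed long/short leg
#'   ratio is within this tolerance of 1 (default 0.1).
#' @param residual_max fit guard: error when the corner residual RMS exceeds
#'   this bound in mm (default 2).
#' @return a [module_pose()].
#' @export
align_module_model <- function(cluster, geometry, normal,
                               ratio_tol = 0.1, residual_max = 2) {
  stopifnot(inherits(geometry, "module_geometry"))
  tri <- measure_fiducial_triangle(cluster)
  ratio <- tri$leg_vertical / tri$leg_horizontal
  if (abs(ratio - 1) < ratio_tol)
    stop(sprintf(paste0("ambiguous fiducial: observed leg ratio %.3f is too ",
                        "close to 1 to orient the module"), ratio),
         call. = FALSE)
  observed <- rbind(tri$corner, tri$horizontal_tip, tri$vertical_tip)
  model <- geometry$triangle_vertices
  fit <- kabsch(model, observed)
  # refine over all cluster points against the model triangle region: the
  # three extremal corners alone are the noisiest members, so a whole-patch
  # least-squares fit markedly reduces the pose noise
  pts <- if (inherits(cluster, "fiducial_cluster")) cluster$points
         else base::matrix(as.numeric(cluster), ncol = 3L)
  if (nrow(pts) > 3L) {
    obj <- function(par) {
      R <- rotation_from_vector(par[4:6]) %*% fit$rotation
      tr <- fit$translation + par[1:3]
      posed <- sweep(model %*% t(R), 2, tr, "+")
      mean(dist2_points_to_triangle(pts, posed[1, ], posed[2, ], posed[3, ]))
    }
    ref <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    fit$rotation <- rotation_from_vector(ref$par[4:6]) %*% fit$rotation
    fit$translation <- fit$translation + ref$par[1:3]
    posed <- sweep(model %*% t(fit$rotation), 2, fit$translation, "+")
    fit$rms <- sqrt(mean(rowSums((posed - observed)^2)))
  }
  pose <- module_pose(fit$rotation, fit$translation, residual_rms = fit$rms)
  if (fit$rms > residual_max)
    stop(sprintf("fiducial fit residual %.2f mm exceeds the %.2f mm bound",
                 fit$rms, residual_max), call. = FALSE)
  # model +z must point away from the head
  outward <- pose$rotation[, 3]
  if (sum(outward * normal) > 0)
    stop("fiducial orientation inconsistent with the inward normal",
         call. = FALSE)
  pose
}

#' Project the module feet into the scan frame
#'
#' @param pose a [module_pose()].
#' @param geometry a [module_geometry()].
#' @return 4 x 3 matrix of foot points (mm).
#' @export
project_feet <- function(pose, geometry) {
  stopifnot(inherits(pose, "module_pose"), inherits(geometry, "module_geometry"))
  pose_apply(pose, geometry$foot_offsets)
}

#' Sparse scalp sample
#'
#' The concatenated projected foot points over all successfully posed
#' modules; the registration target for template fitting.
#'
#' @param points n x 3 matrix of foot points (mm).
#' @param module_ids integer originating cluster per point.
#' @return object of class `sparse_scalp_sample`.
#' @export
sparse_scalp_sample <- function(points, module_ids) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) != length(module_ids))
    stop("`module_ids` must give one id per point", call. = FALSE)
  structure(list(points = points, module_ids = as.integer(module_ids)),
            class = "sparse_scalp_sample")
}

#' @export
print.sparse_scalp_sample <- function(x, ...) {
  cat(sprintf("<sparse_scalp_sample> %d foot points from %d modules\n",
              nrow(x$points), length(unique(x$module_ids))))
  invisible(x)
}

#' Build the sparse scalp sample from a cap scan
#'
#' Runs the detection front end of the pipeline: color filtering, clustering
#' into per-module fiducials, per-module pose recovery, and foot projection.
#' Modules whose pose cannot be recovered are skipped with a warning.
#'
#' @param mesh the cap scan, a [colored_mesh()].
#' @param filter a [color_filter_spec()].
#' @param geometry a [module_geometry()].
#' @param k expected module count (default 17).
#' @param seed clustering seed.
#' @param diameter_bound cluster diameter bound, mm.
#' @param min_modules minimum number of successfully posed modules (default 6)
#'   below which the scan is rejected.
#' @param ... passed on to [align_module_model()].
#' @return a [sparse_scalp_sample()]; attribute `poses` carries the per-module
#'   [module_pose()] objects and attribute `clusters` the fiducial clusters.
#' @export
build_sparse_sample <- function(mesh, filter = color_filter_spec(),
                                geometry = module_geometry(), k = 17L,
                                seed = 1L, diameter_bound = 50,
                                min_modules = 6L, ...) {
  idx <- filter_fiducial_vertices(mesh, filter)
  if (length(idx) < 3L * k)
    stop("too few fiducial vertices after color filtering (",
         length(idx), "); cannot form ", k, " clusters", call. = FALSE)
  clusters <- cluster_fiducials(mesh$vertices[idx, , drop = FALSE], k = k,
                                diameter_bound = diameter_bound, seed = seed,
                                member_indices = idx)
  centroids <- t(vapply(clusters, `[[`, numeric(3), "centroid"))
  head_center <- estimate_head_center(centroids)
  pts <- list(); ids <- integer(0); poses <- vector("list", length(clusters))
  for (j in seq_along(clusters)) {
    pose <- tryCatch({
      ax <- principal_axes(clusters[[j]]$points)
      n <- inward_normal(ax, head_center = head_center)
      align_module_model(clusters[[j]], geometry, n, ...)
    }, error = function(e) {
      warning("module ", j, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    poses[[j]] <- pose
    if (!is.null(pose)) {
      pts[[length(pts) + 1L]] <- project_feet(pose, geometry)
      ids <- c(ids, rep(j, 4L))
    }
  }
  ok <- sum(!vapply(poses, is.null, logical(1)))
  if (ok < min_modules)
    stop("only ", ok, " of ", k, " modules could be posed (minimum ",
         min_modules, ")", call. = FALSE)
  out <- sparse_scalp_sample(do.call(rbind, pts), ids)
  attr(out, "poses") <- poses
  attr(out, "clusters") <- clusters
  attr(out, "head_center") <- head_center
  out
}
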