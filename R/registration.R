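# Spatial transforms and the four surface registrations used by the
# pipeline: label-keyed rigid (10-20 based), four-point affine ("basic 4"),
# unscaled rigid atlas placement, and scaled template-to-sample fitting
# (iterated closest-surface-point with per-axis scale estimation).

#' Homogeneous spatial transform
#'
#' @param matrix 4 x 4 homogeneous transform in mm, bottom row (0, 0, 0, 1).
#' @param kind `"rigid"`, `"affine"` or `"anisotropic_similarity"`. Rigid
#'   transforms must have a proper orthonormal upper 3 x 3 block;
#'   anisotropic similarities factor as `R %*% diag(s)` with positive scales.
#' @return object of class `spatial_transform`.
#' @export
spatial_transform <- function(matrix = diag(4),
                              kind = c("rigid", "affine",
                                       "anisotropic_similarity")) {
  kind <- match.arg(kind)
  m <- base::matrix(as.numeric(matrix), 4L, 4L)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("bottom row of a homogeneous transform must be (0,0,0,1)",
         call. = FALSE)
  L <- m[1:3, 1:3]
  if (kind == "rigid") {
    if (max(abs(crossprod(L) - diag(3))) > 1e-6 || det(L) < 0)
      stop("rigid transform must have a proper orthonormal 3x3 block",
           call. = FALSE)
  } else if (kind == "anisotropic_similarity") {
    f <- polar_rs(L)
    if (any(f$scales <= 0) ||
        max(abs(crossprod(f$rotation) - diag(3))) > 1e-6 ||
        det(f$rotation) < 0)
      stop("anisotropic similarity must factor as R %*% diag(s) with R a ",
           "proper rotation and s > 0", call. = FALSE)
  } else {
    if (abs(det(L)) < 1e-12)
      stop("affine transform must be invertible", call. = FALSE)
  }
  structure(list(matrix = m, kind = kind), class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform> kind: %s\n", x$kind))
  print(round(x$matrix, 6))
  invisible(x)
}

# Factor a 3x3 linear map as R %*% diag(s) (rotation times per-axis scale in
# source axes). Exact when the map has orthogonal columns.
polar_rs <- function(L) {
  s <- sqrt(colSums(L^2))
  R <- L %*% diag(1 / s)
  list(rotation = R, scales = s)
}

transform_compose <- function(a, b) {
  # apply b first, then a
  kind <- if (a$kind == "affine" || b$kind == "affine") "affine"
          else if (a$kind == "rigid" && b$kind == "rigid") "rigid"
          else "anisotropic_similarity"
  m <- a$matrix %*% b$matrix
  tryCatch(spatial_transform(m, kind),
           error = function(e) spatial_transform(m, "affine"))
}

transform_invert <- function(x) {
  spatial_transform(solve(x$matrix), x$kind)
}

transform_points <- function(transform, points) {
  points <- base::matrix(as.numeric(points), ncol = 3L)
  L <- transform$matrix[1:3, 1:3]
  tr <- transform$matrix[1:3, 4]
  sweep(points %*% t(L), 2, tr, "+")
}

#' Apply a spatial transform
#'
#' Maps all coordinates of the object; faces, colors, labels and module ids
#' are unchanged.
#'
#' @param transform a [spatial_transform()].
#' @param object a [colored_mesh()], montage point set, [sparse_scalp_sample()],
#'   [landmark_set()] or plain n x 3 coordinate matrix.
#' @return an object of the same type.
#' @export
apply_transform <- function(transform, object) {
  stopifnot(inherits(transform, "spatial_transform"))
  UseMethod("apply_transform", object)
}

#' @export
apply_transform.default <- function(transform, object) {
  transform_points(transform, object)
}

#' @export
apply_transform.colored_mesh <- function(transform, object) {
  object$vertices <- transform_points(transform, object$vertices)
  object
}

#' @export
apply_transform.sparse_scalp_sample <- function(transform, object) {
  object$points <- transform_points(transform, object$points)
  object
}

#' @export
apply_transform.landmark_set <- function(transform, object) {
  for (nm in names(object))
    object[[nm]] <- drop(transform_points(transform, object[[nm]]))
  object
}

#' @export
apply_transform.montage_points <- function(transform, object) {
  object[, c("x", "y", "z")] <-
    transform_points(transform, as.matrix(object[, c("x", "y", "z")]))
  object
}

#' Write / read a transform as a plain-text 4 x 4 matrix
#'
#' Row-major plain text, mm units; the transform kind is stored on a comment
#' line.
#'
#' @param transform a [spatial_transform()].
#' @param path file path.
#' @return `read_transform` returns a [spatial_transform()].
#' @export
write_transform <- function(transform, path) {
  lines <- c(sprintf("# spatial_transform kind=%s", transform$kind),
             apply(transform$matrix, 1, function(r)
               paste(sprintf("%.12g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kind <- "affine"
  kl <- grep("^#.*kind=", lines, value = TRUE)
  if (length(kl)) kind <- sub("^.*kind=([a-z_]+).*$", "\\1", kl[1])
  lines <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(lines[nzchar(trimws(lines))], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  spatial_transform(m, kind)
}

## ---- rigid from labeled correspondences ----------------------------------

# Least-squares rigid fit (Kabsch) mapping P onto Q.
kabsch <- function(P, Q) {
  P <- base::matrix(as.numeric(P), ncol = 3L)
  Q <- base::matrix(as.numeric(Q), ncol = 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cq - drop(R %*% cp)
  res <- sweep(P %*% t(R), 2, tr, "+") - Q
  list(rotation = R, translation = tr,
       rms = sqrt(mean(rowSums(res^2))))
}

transform_from_rt <- function(R, tr, kind = "rigid") {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- tr
  spatial_transform(m, kind)
}

montage_xyz <- function(m) as.matrix(m[, c("x", "y", "z")])

#' Rigid registration from labeled 10-20 correspondences
#'
#' Least-squares rigid transform (rotation and translation only, no scale)
#' mapping the source montage onto the target, using the labels shared by
#' both point sets as correspondences. This is the alignment used before
#' error assessment: because montage points are placed by surface geodesics
#' without reference to the cap, they give an independent correspondence
#' between a scalp estimate and a measured head surface.
#'
#' @param source,target montage point sets (see [compute_1020()]) or
#'   data frames with `label`, `x`, `y`, `z` columns.
#' @return a rigid [spatial_transform()] with attributes `rms` and `labels`.
#' @export
rigid_from_correspondences <- function(source, target) {
  shared <- intersect(source$label, target$label)
  if (length(shared) < 3L)
    stop("too few shared labels (", length(shared),
         "); at least 3 are required", call. = FALSE)
  P <- montage_xyz(source[match(shared, source$label), ])
  Q <- montage_xyz(target[match(shared, target$label), ])
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("degenerate correspondence set: shared points are collinear",
         call. = FALSE)
  fit <- kabsch(P, Q)
  out <- transform_from_rt(fit$rotation, fit$translation, "rigid")
  attr(out, "rms") <- fit$rms
  attr(out, "labels") <- shared
  out
}

#' Unscaled rigid atlas placement
#'
#' Registers an unscaled atlas to a participant-specific scalp via the
#' corresponding 10-20 points with a rigid transform (translation and
#' rotation only). The contract is that of [rigid_from_correspondences()];
#' the separate name records the distinct provenance of this comparison
#' method in reports.
#'
#' @inheritParams rigid_from_correspondences
#' @return a rigid [spatial_transform()].
#' @export
unscaled_atlas_placement <- function(source, target) {
  out <- rigid_from_correspondences(source, target)
  attr(out, "method") <- "unscaled_atlas"
  out
}

## ---- four-point affine ----------------------------------------------------

#' "Basic 4" four-point affine transform
#'
#' The unique affine transform mapping four labeled source points exactly to
#' their targets (nasion, inion and the two tragus/preauricular points in the
#' basic-4 strategy). Requires the source points to be non-coplanar.
#'
#' @param source,target 4 x 3 matrices (or landmark sets) in corresponding
#'   row order.
#' @return an affine [spatial_transform()].
#' @export
affine_from_4_points <- function(source, target) {
  if (inherits(source, "landmark_set")) source <- landmark_matrix(source)
  if (inherits(target, "landmark_set")) target <- landmark_matrix(target)
  source <- base::matrix(as.numeric(source), ncol = 3L)
  target <- base::matrix(as.numeric(target), ncol = 3L)
  if (nrow(source) != 4L || nrow(target) != 4L)
    stop("exactly four source and target points are required", call. = FALSE)
  A <- cbind(source, 1)
  vol <- abs(det(A)) / 6   # volume of the source tetrahedron
  if (vol < 1e-6)
    stop(sprintf(paste0("coplanar source points: tetrahedron volume %.3g mm^3",
                        " is too small for a well-defined affine transform"),
                 vol), call. = FALSE)
  X <- solve(A, target)    # 4 x 3; rows 1:3 linear part (transposed), row 4 t
  m <- diag(4)
  m[1:3, 1:3] <- t(X[1:3, ])
  m[1:3, 4] <- X[4, ]
  out <- spatial_transform(m, "affine")
  attr(out, "source_volume") <- vol
  out
}

## ---- similarity from landmark pairs (initialisation helper) ---------------

# Rigid + isotropic-scale fit of paired landmark sets (used to initialise the
# template fit from operator-picked cranial landmarks).
similarity_from_landmarks <- function(source, target) {
  if (inherits(source, "landmark_set")) source <- landmark_matrix(source)
  if (inherits(target, "landmark_set")) target <- landmark_matrix(target)
  P <- base::matrix(as.numeric(source), ncol = 3L)
  Q <- base::matrix(as.numeric(target), ncol = 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- sqrt(sum(Qc^2) / sum(Pc^2))
  fit <- kabsch(P * s, Q)
  m <- diag(4)
  m[1:3, 1:3] <- fit$rotation * s
  m[1:3, 4] <- fit$translation
  spatial_transform(m, "anisotropic_similarity")
}

## ---- scaled template-to-sample fitting ------------------------------------

#' Fit a template head surface to a sparse scalp sample
#'
#' Iterated closest-surface-point fitting of a template mesh to the projected
#' module-foot points: each iteration finds the closest point on the
#' transformed template surface for every sample point, then re-estimates the
#' transform (rotation + translation, optionally with isotropic or per-axis
#' scale in template axes) minimizing the summed squared correspondence
#' distances. The objective (mean squared point-to-surface distance) is
#' non-increasing across iterations; iteration stops when it improves by less
#' than `tol` mm^2.
#'
#' @param template a [colored_mesh()] head surface.
#' @param sample a [sparse_scalp_sample()] or n x 3 point matrix (n >= 12,
#'   spread over more than one octant around the template).
#' @param allow_scaling `"none"` (rigid), `"isotropic"`, `"anisotropic"`, or
#'   `"affine"` (full 12-parameter fit, used for dense volumetric-style
#'   registration).
#' @param init optional initial [spatial_transform()] (e.g. from
#'   [similarity_from_landmarks()]); identity by default.
#' @param max_iter iteration budget (default 150).
#' @param tol convergence threshold on the objective improvement, mm^2
#'   (default 1e-4).
#' @return a [spatial_transform()] (kind `"rigid"` for `"none"`, otherwise
#'   `"anisotropic_similarity"`), with attributes `rms` (final RMS
#'   point-to-surface distance, mm), `objective_trace` and `iterations`.
#' @export
fit_template_to_sample <- function(template, sample,
                                   allow_scaling = c("anisotropic",
                                                     "isotropic", "none",
                                                     "affine"),
                                   init = NULL, max_iter = 150L, tol = 1e-4) {
  allow_scaling <- match.arg(allow_scaling)
  pts <- if (inherits(sample, "sparse_scalp_sample")) sample$points
         else base::matrix(as.numeric(sample), ncol = 3L)
  if (nrow(pts) < 12L)
    stop("insufficient sample: ", nrow(pts),
         " points (at least 12 are required)", call. = FALSE)
  if (is.null(init)) init <- spatial_transform(diag(4), "rigid")

  # octant-coverage check in the initialised template frame
  ctr <- colMeans(template$vertices)
  rel <- sweep(transform_points(transform_invert(init), pts), 2, ctr)
  octants <- unique(paste(rel[, 1] > 0, rel[, 2] > 0, rel[, 3] > 0))
  if (length(octants) < 2L)
    stop("insufficient sample spread: all points fall in one octant around ",
         "the template", call. = FALSE)

  # work with the template centred at its centroid so scales act about a
  # meaningful origin; compose the centring back in at the end
  V0 <- sweep(template$vertices, 2, ctr)
  faces <- template$faces

  ini <- init$matrix
  L <- ini[1:3, 1:3]
  if (allow_scaling == "none") {
    sc <- sqrt(colSums(L^2))
    L <- L %*% diag(1 / sc)   # strip any scale carried by the init
  }
  tr <- ini[1:3, 4] + drop(ini[1:3, 1:3] %*% ctr)

  mesh_t <- colored_mesh(V0, faces)
  cache <- closest_point_cache(mesh_t)
  obj_trace <- numeric(0)
  prev_obj <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    mesh_t$vertices <- sweep(V0 %*% t(L), 2, tr, "+")
    cp <- closest_point_on_mesh(pts, mesh_t, cache = cache,
                                edge_scale = svd(L)$d[1] * 1.01)
    obj <- mean(cp$distance^2)
    obj_trace <- c(obj_trace, obj)
    if (prev_obj - obj < tol || it >= max_iter) break
    prev_obj <- obj
    # pull correspondences back to the (centred) template frame
    M <- sweep(cp$points, 2, tr) %*% t(solve(L))
    if (allow_scaling == "affine") {
      A <- cbind(M, 1)
      X <- solve(crossprod(A), crossprod(A, pts))
      L <- t(X[1:3, ]); tr <- X[4, ]
    } else {
      f0 <- polar_rs(L)
      R <- f0$rotation
      S <- if (allow_scaling == "none") c(1, 1, 1) else f0$scales
      for (inner in 1:3) {
        f <- kabsch(M %*% diag(S), pts)
        R <- f$rotation; tr <- f$translation
        if (allow_scaling == "none") break
        B <- sweep(pts, 2, tr) %*% R   # == R^T (p - t), row-wise
        if (allow_scaling == "isotropic") {
          s1 <- sum(B * M) / sum(M * M)
          S <- rep(max(s1, 1e-6), 3L)
        } else {
          S <- pmax(colSums(B * M) / colSums(M * M), 1e-6)
        }
      }
      L <- R %*% diag(S)
    }
  }
  if (it >= max_iter && prev_obj - obj >= tol)
    warning("template fit did not converge within ", max_iter, " iterations",
            call. = FALSE)
  m <- diag(4)
  m[1:3, 1:3] <- L
  m[1:3, 4] <- tr - drop(L %*% ctr)
  out <- spatial_transform(m, switch(allow_scaling, none = "rigid",
                                     affine = "affine",
                                     "anisotropic_similarity"))
  attr(out, "rms") <- sqrt(obj)
  attr(out, "objective_trace") <- obj_trace
  attr(out, "iterations") <- it
  out
}
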