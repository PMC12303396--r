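# Core mesh and landmark containers plus the small vector-geometry toolbox the
# rest of the package is built on. All coordinates are millimetres; internally
# generated data uses a right-handed frame with the nose toward +Y, the left
# ear toward -X and the vertex toward +Z. External meshes are used as-is.

#' Colored triangulated surface mesh
#'
#' Container for a triangulated surface with per-vertex RGB color, the common
#' currency of the pipeline: the 3D scan of the cap, template head surfaces and
#' synthetic phantoms are all `colored_mesh` objects.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param colors numeric matrix, one row per vertex, RGB channels in `[0, 1]`.
#'   A single color may be given as a length-3 vector and is recycled.
#' @return An object of class `colored_mesh` with elements `vertices`, `faces`
#'   and `colors`.
#' @export
colored_mesh <- function(vertices, faces, colors = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L)
    stop("`vertices` must have three columns (x, y, z in mm)", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("`vertices` must be finite", call. = FALSE)
  if (is.null(faces) || length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(faces) != 3L)
    stop("`faces` must have three columns of vertex indices", call. = FALSE)
  if (nrow(faces) > 0L) {
    if (nrow(vertices) < 3L)
      stop("a mesh with faces needs at least 3 vertices", call. = FALSE)
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices must point at existing vertices", call. = FALSE)
  }
  if (is.null(colors)) colors <- c(0.7, 0.7, 0.7)
  if (is.vector(colors) && length(colors) == 3L)
    colors <- matrix(colors, nrow(vertices), 3L, byrow = TRUE)
  colors <- as.matrix(colors)
  storage.mode(colors) <- "double"
  dimnames(colors) <- NULL
  if (nrow(colors) != nrow(vertices) || ncol(colors) != 3L)
    stop("`colors` must be an n_vertices x 3 matrix", call. = FALSE)
  if (any(!is.finite(colors)) || min(colors) < 0 || max(colors) > 1)
    stop("color channels must lie in [0, 1]", call. = FALSE)
  structure(list(vertices = vertices, faces = faces, colors = colors),
            class = "colored_mesh")
}

#' @export
print.colored_mesh <- function(x, ...) {
  cat(sprintf("<colored_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Cranial landmark set
#'
#' The four cranial landmarks used to anchor geodesic electrode montages:
#' nasion, inion, and the left/right preauricular points.
#'
#' @param nasion,inion,left_preauricular,right_preauricular length-3 numeric
#'   vectors in mm.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(nasion, inion, left_preauricular, right_preauricular) {
  pts <- rbind(nasion = as.numeric(nasion), inion = as.numeric(inion),
               left_preauricular = as.numeric(left_preauricular),
               right_preauricular = as.numeric(right_preauricular))
  if (ncol(pts) != 3L || !all(is.finite(pts)))
    stop("landmarks must be finite 3D points", call. = FALSE)
  d <- as.matrix(stats::dist(pts))
  if (any(d[upper.tri(d)] < 1e-9))
    stop("landmarks must be pairwise distinct", call. = FALSE)
  # collinearity check: rank of centred coordinates must exceed 1
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("the four landmarks must not be collinear", call. = FALSE)
  structure(list(nasion = pts[1, ], inion = pts[2, ],
                 left_preauricular = pts[3, ], right_preauricular = pts[4, ]),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-18s % 8.2f % 8.2f % 8.2f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

landmark_matrix <- function(landmarks) {
  rbind(nasion = landmarks$nasion, inion = landmarks$inion,
        left_preauricular = landmarks$left_preauricular,
        right_preauricular = landmarks$right_preauricular)
}

## ---- small vector toolbox ------------------------------------------------

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) m / pmax(row_norms(m), 1e-300)

## ---- mesh utilities ------------------------------------------------------

#' Per-vertex outward normals
#'
#' Area-weighted average of incident face normals. Orientation follows the
#' face winding, which for meshes generated by this package is outward.
#'
#' @param mesh a [colored_mesh()].
#' @return n_vertices x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], group = f[, j], reorder = FALSE)
      n[as.integer(rownames(acc)), k] <- n[as.integer(rownames(acc)), k] + acc[, 1]
    }
  }
  normalize_rows(n)
}

# Undirected edge list as a 2-column matrix of sorted vertex index pairs.
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# TRUE when every edge is shared by exactly two faces.
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  e <- mesh_edges(mesh$faces)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  mean(row_norms(mesh$vertices[e[, 1], , drop = FALSE] -
                 mesh$vertices[e[, 2], , drop = FALSE]))
}

# Signed volume via the divergence theorem; positive for outward winding.
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Merge several colored meshes into one (concatenation with index offsets).
merge_meshes <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  vs <- lapply(parts, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  fs <- mapply(function(p, o) p$faces + o, parts, off[-length(off)],
               SIMPLIFY = FALSE)
  colored_mesh(do.call(rbind, vs), do.call(rbind, fs),
               do.call(rbind, lapply(parts, `[[`, "colors")))
}

## ---- closest point on a triangulated surface -----------------------------

# Closest points on a set of triangles (A, B, C row-wise) to a single query
# point p. Vectorized version of the standard closest-point-on-triangle
# region test. Returns an n x 3 matrix.
closest_point_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  out <- matrix(NA_real_, nrow(A), 3L)
  done <- rep(FALSE, nrow(A))

  set <- function(idx, val) {
    if (any(idx)) out[idx, ] <<- val[idx, , drop = FALSE]
    done <<- done | idx
  }
  set(!done & d1 <= 0 & d2 <= 0, A)
  set(!done & d3 >= 0 & d4 <= d3, B)
  set(!done & d6 >= 0 & d5 <= d6, C)
  vc <- d1 * d4 - d3 * d2
  w <- d1 / pmax(d1 - d3, 1e-300)
  set(!done & vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * w)
  vb <- d5 * d2 - d1 * d6
  w <- d2 / pmax(d2 - d6, 1e-300)
  set(!done & vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * w)
  va <- d3 * d6 - d5 * d4
  w <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  set(!done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * w)
  if (any(!done)) {
    denom <- 1 / (va + vb + vc)
    v <- vb * denom; w2 <- vc * denom
    out[!done, ] <- (A + ab * v + ac * w2)[!done, , drop = FALSE]
  }
  out
}

# Topology cache for repeated closest-point queries against meshes sharing
# one face structure (e.g. a template under a changing transform).
closest_point_cache <- function(mesh) {
  f <- mesh$faces
  e <- mesh_edges(f)
  v <- mesh$vertices
  vf <- split(rep(seq_len(nrow(f)), 3L),
              factor(as.vector(f), levels = seq_len(nrow(v))))
  list(vert_faces = vf,
       maxedge = sqrt(max(rowSums((v[e[, 1], , drop = FALSE] -
                                   v[e[, 2], , drop = FALSE])^2))))
}

# Closest surface points on `mesh` for each row of `points`. Exact within the
# candidate set selected by a nearest-vertex prefilter (all faces touching a
# vertex within the nearest-vertex distance plus twice the longest edge, which
# is a superset of the faces that can carry the true closest point).
#
# Returns list(points, distance, face).
closest_point_on_mesh <- function(points, mesh, prefilter = TRUE,
                                  cache = NULL, edge_scale = 1) {
  points <- matrix(as.numeric(points), ncol = 3L)
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) stop("mesh has no faces", call. = FALSE)
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  use_pf <- prefilter && nf > 200L
  if (use_pf) {
    if (is.null(cache)) cache <- closest_point_cache(mesh)
    maxedge <- cache$maxedge * edge_scale
    vert_faces <- cache$vert_faces
  }
  n <- nrow(points)
  cp <- matrix(NA_real_, n, 3L)
  dist <- numeric(n)
  face <- integer(n)
  if (use_pf) {
    # all point-vertex squared distances in one pass
    D2 <- outer(rowSums(v * v), rowSums(points * points), "+") -
      2 * tcrossprod(v, points)
  }
  for (i in seq_len(n)) {
    p <- points[i, ]
    if (use_pf) {
      dv2 <- D2[, i]
      rad <- sqrt(max(min(dv2), 0)) + 2 * maxedge
      cand_v <- which(dv2 <= rad * rad)
      cand <- unique(unlist(vert_faces[cand_v], use.names = FALSE))
    } else cand <- seq_len(nf)
    q <- closest_point_triangles(p, A[cand, , drop = FALSE],
                                 B[cand, , drop = FALSE], C[cand, , drop = FALSE])
    d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2
    j <- which.min(d2)
    cp[i, ] <- q[j, ]
    dist[i] <- sqrt(d2[j])
    face[i] <- cand[j]
  }
  list(points = cp, distance = dist, face = face)
}
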