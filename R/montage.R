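# Geodesic construction of 10-20 and modified 10-5 electrode montages on a
# head surface, anchored at the four cranial landmarks.
#
# Curves are plane-slice geodesics: the intersection of the mesh with the
# plane through the two endpoints and a reference point, restricted to the
# arc passing nearest the reference. Electrode sites are placed at arc-length
# fractions of these curves:
#
#   * the sagittal curve nasion -> inion (through Cz) carries the midline,
#   * the ear-level ring passes through Fpz, T7, Oz, T8,
#   * one transverse row per midline level runs from a left ring point
#     through the midline point to the mirrored right ring point, with the
#     ring anchor at the same arc fraction as the midline level (the
#     classical correspondence: the F row ends at F7, the ring point at the
#     Fz level).
#
# The modified 10-5 montage used for error assessment is the 17 x 17 grid of
# 17 midline levels (10%..90% in 5% steps) by 17 columns per row (eighths of
# each half-row), which has exactly 289 labels and contains the 21 standard
# 10-20 sites as grid cells.

## ---- plane slicing -------------------------------------------------------

# Intersect a triangulated mesh with a plane. Returns a list of polylines
# (list(points, closed)); each polyline visits the plane/edge crossing points
# in order. Signed distances exactly at zero are nudged so every crossing
# face has exactly two crossed edges.
slice_mesh_plane <- function(mesh, p0, n) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- drop(sweep(v, 2, p0) %*% n)
  d[abs(d) < 1e-12] <- 1e-12
  pos <- d > 0
  s1 <- pos[f[, 1]]; s2 <- pos[f[, 2]]; s3 <- pos[f[, 3]]
  crossing <- !(s1 == s2 & s2 == s3)
  if (!any(crossing)) return(list())
  fc <- f[crossing, , drop = FALSE]
  cs <- cbind(pos[fc[, 1]], pos[fc[, 2]], pos[fc[, 3]])
  # crossed edges per face, as canonical vertex pairs
  edge_of <- function(i, j) {
    a <- fc[cbind(seq_len(nrow(fc)), i)]
    b <- fc[cbind(seq_len(nrow(fc)), j)]
    cbind(pmin(a, b), pmax(a, b))
  }
  e12 <- edge_of(1L, 2L); e23 <- edge_of(2L, 3L); e31 <- edge_of(3L, 1L)
  x12 <- cs[, 1] != cs[, 2]; x23 <- cs[, 2] != cs[, 3]; x31 <- cs[, 3] != cs[, 1]
  # each crossing face has exactly two of x12/x23/x31 TRUE
  first_e <- ifelse(x12, 1L, 2L)                 # 1 = e12, 2 = e23
  second_e <- ifelse(x31, 3L, 2L)                # 3 = e31, 2 = e23
  pick <- function(which_e, row) switch(which_e, e12[row, ], e23[row, ], e31[row, ])
  nfc <- nrow(fc)
  ea <- matrix(0L, nfc, 2L); eb <- matrix(0L, nfc, 2L)
  for (r in seq_len(nfc)) {
    ea[r, ] <- pick(first_e[r], r)
    eb[r, ] <- pick(second_e[r], r)
  }
  all_e <- rbind(ea, eb)
  key <- paste(all_e[, 1], all_e[, 2])
  ukey <- unique(key)
  eidx <- match(key, ukey)
  ea_i <- eidx[seq_len(nfc)]
  eb_i <- eidx[nfc + seq_len(nfc)]
  # crossing point per unique edge
  ue <- all_e[match(ukey, key), , drop = FALSE]
  di <- d[ue[, 1]]; dj <- d[ue[, 2]]
  t <- di / (di - dj)
  cross_pts <- v[ue[, 1], , drop = FALSE] +
    (v[ue[, 2], , drop = FALSE] - v[ue[, 1], , drop = FALSE]) * t
  # faces sharing each edge (1 or 2 for manifold meshes)
  ne <- length(ukey)
  face1 <- integer(ne); face2 <- integer(ne)
  note_face <- function(ei, fi) {
    for (k in seq_along(ei)) {
      e <- ei[k]
      if (face1[e] == 0L) face1[e] <<- fi[k]
      else if (face2[e] == 0L) face2[e] <<- fi[k]
    }
  }
  note_face(ea_i, seq_len(nfc))
  note_face(eb_i, seq_len(nfc))
  other_face <- function(e, fi) {
    if (face1[e] == fi) face2[e] else face1[e]
  }
  used <- logical(nfc)
  loops <- list()
  for (start in seq_len(nfc)) {
    if (used[start]) next
    walk <- function(entry_edge) {
      # returns the edge sequence visited from `start` entering via entry_edge
      seq_e <- integer(0)
      cur <- start
      ein <- entry_edge
      repeat {
        used[cur] <<- TRUE
        eout <- if (ea_i[cur] == ein) eb_i[cur] else ea_i[cur]
        seq_e <- c(seq_e, eout)
        nxt <- other_face(eout, cur)
        if (nxt == 0L) return(list(edges = seq_e, open = TRUE))
        if (nxt == start) return(list(edges = seq_e, open = FALSE))
        cur <- nxt
        ein <- eout
      }
    }
    fwd <- walk(ea_i[start])
    if (!fwd$open) {
      edges <- c(ea_i[start], fwd$edges)
      # last exit edge re-enters the start face: drop the duplicate
      if (edges[length(edges)] == edges[1]) edges <- edges[-length(edges)]
      loops[[length(loops) + 1L]] <-
        list(points = cross_pts[edges, , drop = FALSE], closed = TRUE)
    } else {
      bwd <- walk(eb_i[start])
      edges <- c(rev(fwd$edges), ea_i[start], bwd$edges)
      loops[[length(loops) + 1L]] <-
        list(points = cross_pts[edges, , drop = FALSE], closed = FALSE)
    }
  }
  loops
}

## ---- polyline helpers ----------------------------------------------------

polyline_cumlen <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  c(0, cumsum(row_norms(pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])))
}

# closest point on an (open) polyline; returns arc position and coordinates
project_to_polyline <- function(pts, p) {
  m <- nrow(pts)
  if (m == 1L)
    return(list(s = 0, point = pts[1, ], dist = vnorm(p - pts[1, ])))
  a <- pts[-m, , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  t <- pmin(pmax(rowSums(sweep(-a, 2, p, "+") * ab) / len2, 0), 1)
  q <- a + ab * t
  d2 <- rowSums(sweep(q, 2, p)^2)
  j <- which.min(d2)
  cum <- polyline_cumlen(pts)
  list(s = cum[j] + t[j] * sqrt(len2[j]), point = q[j, ], dist = sqrt(d2[j]))
}

# distance from point p to a loop/polyline (closed handled by caller append)
polyline_min_dist <- function(pts, p) project_to_polyline(pts, p)$dist

loop_as_open <- function(loop) {
  if (loop$closed) rbind(loop$points, loop$points[1, , drop = FALSE])
  else loop$points
}

# point at arc position s (mod total length) on a closed loop
loop_point_at <- function(pts_open, cum, s) {
  L <- cum[length(cum)]
  s <- s %% L
  j <- max(findInterval(s, cum, rightmost.closed = TRUE), 1L)
  if (j >= length(cum)) j <- length(cum) - 1L
  seg <- cum[j + 1L] - cum[j]
  t <- if (seg > 0) (s - cum[j]) / seg else 0
  pts_open[j, ] + t * (pts_open[j + 1L, ] - pts_open[j, ])
}

# forward sub-path of a closed loop from arc position s_a to s_b
loop_subpath <- function(pts_open, cum, s_a, s_b) {
  L <- cum[length(cum)]
  arc <- (s_b - s_a) %% L
  if (arc == 0) arc <- L
  m <- nrow(pts_open) - 1L           # unique vertices
  ext_s <- c(cum[seq_len(m)], cum[seq_len(m)] + L)
  ext_i <- c(seq_len(m), seq_len(m))
  eps <- 1e-9 * max(L, 1)
  sel <- ext_s > s_a + eps & ext_s < s_a + arc - eps
  mid <- pts_open[ext_i[sel], , drop = FALSE]
  rbind(loop_point_at(pts_open, cum, s_a), mid,
        loop_point_at(pts_open, cum, s_b))
}

## ---- geodesic curves -----------------------------------------------------

#' Plane-slice geodesic curve between two surface points
#'
#' Intersects the mesh with the plane through `a`, `b` and `through`, and
#' returns the arc from `a` to `b` that passes nearest `through`, as a
#' polyline with its arc length.
#'
#' @param mesh a [colored_mesh()].
#' @param a,b curve endpoints on (or near) the surface, length-3 vectors.
#' @param through reference point fixing the slicing plane and selecting
#'   which of the two arcs is returned.
#' @return list with `points` (polyline matrix from `a` to `b`) and `length`
#'   (mm).
#' @export
geodesic_curve <- function(mesh, a, b, through) {
  a <- as.numeric(a); b <- as.numeric(b); through <- as.numeric(through)
  if (vnorm(b - a) < 1e-9)
    return(list(points = rbind(a, a), length = 0))
  n <- cross3(b - a, through - a)
  if (vnorm(n) < 1e-9 * max(vnorm(b - a), 1))
    stop("`through` is collinear with the endpoints; slicing plane undefined",
         call. = FALSE)
  n <- n / vnorm(n)
  loops <- slice_mesh_plane(mesh, a, n)
  if (length(loops) == 0L)
    stop("the slicing plane does not intersect the mesh", call. = FALSE)
  score <- vapply(loops, function(l) {
    o <- loop_as_open(l)
    polyline_min_dist(o, a) + polyline_min_dist(o, b)
  }, numeric(1))
  loop <- loops[[which.min(score)]]
  tol <- 2 * mean_edge_length(mesh) + 1
  o <- loop_as_open(loop)
  pa <- project_to_polyline(o, a)
  pb <- project_to_polyline(o, b)
  if (pa$dist > tol || pb$dist > tol)
    stop("no surface arc between the endpoints: nearest slice curve is ",
         sprintf("%.1f mm away", max(pa$dist, pb$dist)), call. = FALSE)
  if (!loop$closed)
    stop("open surface: the slice curve is interrupted between the endpoints",
         call. = FALSE)
  cum <- polyline_cumlen(o)
  arc1 <- loop_subpath(o, cum, pa$s, pb$s)
  arc2 <- loop_subpath(o, cum, pb$s, pa$s)
  arc2 <- arc2[rev(seq_len(nrow(arc2))), , drop = FALSE]
  d1 <- polyline_min_dist(arc1, through)
  d2 <- polyline_min_dist(arc2, through)
  pts <- if (d1 <= d2) arc1 else arc2
  list(points = pts, length = polyline_cumlen(pts)[nrow(pts)])
}

#' Point at an arc-length fraction of a curve
#'
#' @param curve result of [geodesic_curve()] (or any list with a `points`
#'   polyline).
#' @param fraction arc-length fraction in `[0, 1]`.
#' @return length-3 point.
#' @export
fractional_point <- function(curve, fraction) {
  pts <- curve$points
  if (nrow(pts) < 2L) return(pts[1, ])
  fraction <- min(max(fraction, 0), 1)
  cum <- polyline_cumlen(pts)
  L <- cum[length(cum)]
  if (L == 0) return(pts[1, ])
  s <- fraction * L
  j <- max(findInterval(s, cum, rightmost.closed = TRUE), 1L)
  if (j >= length(cum)) j <- length(cum) - 1L
  seg <- cum[j + 1L] - cum[j]
  t <- if (seg > 0) (s - cum[j]) / seg else 0
  pts[j, ] + t * (pts[j + 1L, ] - pts[j, ])
}

# split an open curve at the projection of `point`; returns the two halves
curve_split <- function(curve, point) {
  pts <- curve$points
  pr <- project_to_polyline(pts, point)
  cum <- polyline_cumlen(pts)
  before <- pts[cum < pr$s - 1e-9, , drop = FALSE]
  after <- pts[cum > pr$s + 1e-9, , drop = FALSE]
  list(first = list(points = rbind(before, pr$point)),
       second = list(points = rbind(pr$point, after)))
}

## ---- Cz iteration --------------------------------------------------------

#' Locate the vertex electrode Cz
#'
#' Alternating refinement of Cz as the mutual midpoint of the sagittal
#' (nasion-inion) and coronal (preauricular) plane-slice curves. Starting
#' from the top-of-head point above the nasion-inion midpoint, each round
#' takes the midpoint of the sagittal curve through the current Cz, then the
#' midpoint of the coronal curve through that point.
#'
#' @param mesh a [colored_mesh()].
#' @param landmarks a [landmark_set()].
#' @param tol convergence tolerance on the Cz update, mm (default 0.5).
#' @param max_iter iteration budget (default 20).
#' @return list with `cz`, the converged `sagittal` and `coronal` curves, and
#'   `iterations`.
#' @export
locate_cz <- function(mesh, landmarks, tol = 0.5, max_iter = 20L) {
  nas <- landmarks$nasion; ini <- landmarks$inion
  lpa <- landmarks$left_preauricular; rpa <- landmarks$right_preauricular
  up <- cross3(rpa - lpa, nas - ini)
  up <- up / vnorm(up)
  mid <- (nas + ini) / 2
  span <- max(row_norms(sweep(mesh$vertices, 2, mid)))
  cz <- drop(closest_point_on_mesh(mid + up * 2 * span, mesh)$points)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    sag <- geodesic_curve(mesh, nas, ini, cz)
    m1 <- fractional_point(sag, 0.5)
    cor <- geodesic_curve(mesh, lpa, rpa, m1)
    m2 <- fractional_point(cor, 0.5)
    if (vnorm(m2 - cz) < tol) { cz <- m2; converged <- TRUE; break }
    cz <- m2
  }
  if (!converged)
    stop("Cz iteration did not converge within ", max_iter, " iterations",
         call. = FALSE)
  list(cz = cz,
       sagittal = geodesic_curve(mesh, nas, ini, cz),
       coronal = geodesic_curve(mesh, lpa, rpa, cz),
       iterations = iterations)
}

## ---- label registry ------------------------------------------------------

ten5_row_prefixes <- c("Fp", "AFp", "AF", "AFF", "F", "FFC", "FC", "FCC", "C",
                       "CCP", "CP", "CPP", "P", "PPO", "PO", "POO", "O")
ten5_col_codes <- c("7", "7h", "5", "5h", "3", "3h", "1", "1h", "z",
                    "2h", "2", "4h", "4", "6h", "6", "8h", "8")
# The Fp and O rows hug the ring, where the classical lateral label is 1/2
# (Fp1, O1, ...), not 7/8; their interior columns step a..g toward midline.
ten5_col_codes_ring <- c("1", "1a", "1b", "1c", "1d", "1e", "1f", "1g", "z",
                         "2g", "2f", "2e", "2d", "2c", "2b", "2a", "2")

#' The frozen modified 10-5 label registry
#'
#' The 289 labels of the modified 10-5 montage used for error assessment: a
#' 17 x 17 grid of 17 midline levels (nasion-inion fractions 0.10 to 0.90 in
#' 0.05 steps) by 17 columns per transverse row (eighths of each half-row
#' from the left ring anchor through the midline to the right ring anchor).
#' Naming follows the extended 10-10/10-5 convention: row prefix (Fp, AFp,
#' AF, ..., O) plus column code (7, 5, 3, 1, z, 2, 4, 6, 8 at the 10-10
#' columns, with an `h` suffix for the half-step columns); the classical
#' lateral exceptions are kept (T7/T8, FT, TP, FTT, TTP in the temporal
#' region and Fp1/Fp2, O1/O2 on the ring).
#'
#' All 21 labels of the 10-20 montage appear in this registry. The exact
#' membership of the modified 10-5 subset is this package's own frozen
#' definition (shipped as `inst/extdata/ten5_labels.txt`); only its
#' cardinality, 289, is externally anchored.
#'
#' @return data frame with `label`, `level` (midline fraction) and `column`
#'   (0..16), in canonical order.
#' @export
ten5_label_grid <- function() {
  levels <- seq(0.10, 0.90, by = 0.05)
  grid <- expand.grid(column = 0:16, level_index = 1:17,
                      KEEP.OUT.ATTRS = FALSE)
  prefix <- ten5_row_prefixes[grid$level_index]
  ring_row <- prefix %in% c("Fp", "O")
  code <- ifelse(ring_row, ten5_col_codes_ring[grid$column + 1L],
                 ten5_col_codes[grid$column + 1L])
  label <- paste0(prefix, code)
  special <- c("C.0" = "T7", "C.16" = "T8",
               "FC.0" = "FT7", "FC.16" = "FT8",
               "CP.0" = "TP7", "CP.16" = "TP8",
               "FCC.0" = "FTT7", "FCC.16" = "FTT8",
               "CCP.0" = "TTP7", "CCP.16" = "TTP8")
  key <- paste0(prefix, ".", grid$column)
  hit <- key %in% names(special)
  label[hit] <- special[key[hit]]
  data.frame(label = label, level = levels[grid$level_index],
             column = grid$column, stringsAsFactors = FALSE)
}

#' @rdname ten5_label_grid
#' @export
ten5_labels <- function() ten5_label_grid()$label

ten20_cells <- function() {
  data.frame(
    label = c("Fp1", "Fpz", "Fp2",
              "F7", "F3", "Fz", "F4", "F8",
              "T7", "C3", "Cz", "C4", "T8",
              "P7", "P3", "Pz", "P4", "P8",
              "O1", "Oz", "O2"),
    level = c(0.1, 0.1, 0.1,
              0.3, 0.3, 0.3, 0.3, 0.3,
              0.5, 0.5, 0.5, 0.5, 0.5,
              0.7, 0.7, 0.7, 0.7, 0.7,
              0.9, 0.9, 0.9),
    column = c(0L, 8L, 16L,
               0L, 4L, 8L, 12L, 16L,
               0L, 4L, 8L, 12L, 16L,
               0L, 4L, 8L, 12L, 16L,
               0L, 8L, 16L),
    stringsAsFactors = FALSE)
}

## ---- montage point sets --------------------------------------------------

#' Labeled montage point set
#'
#' @param labels character vector of electrode labels (unique).
#' @param positions n x 3 matrix of 3D positions (mm).
#' @param montage_id `"ten20"` (21 labels) or `"ten5_above_ears"`
#'   (289 labels).
#' @return data frame of class `montage_points` with columns `label`, `x`,
#'   `y`, `z` and attribute `montage_id`.
#' @export
montage_points <- function(labels, positions, montage_id) {
  positions <- base::matrix(as.numeric(positions), ncol = 3L)
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("montage labels must be unique", call. = FALSE)
  if (length(labels) != nrow(positions))
    stop("one position per label required", call. = FALSE)
  expected <- c(ten20 = 21L, ten5_above_ears = 289L)
  if (montage_id %in% names(expected) &&
      length(labels) != expected[[montage_id]])
    stop(montage_id, " montage must have ", expected[[montage_id]],
         " labels, got ", length(labels), call. = FALSE)
  out <- data.frame(label = labels, x = positions[, 1], y = positions[, 2],
                    z = positions[, 3], stringsAsFactors = FALSE)
  class(out) <- c("montage_points", "data.frame")
  attr(out, "montage_id") <- montage_id
  out
}

#' Write / read a montage as plain text
#'
#' One line per electrode: `label x y z` in mm.
#'
#' @param montage a [montage_points()] set.
#' @param path file path.
#' @param montage_id montage identity to assign on read.
#' @export
write_montage <- function(montage, path) {
  writeLines(sprintf("%s %.6f %.6f %.6f", montage$label, montage$x,
                     montage$y, montage$z), path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path, montage_id = NULL) {
  tok <- strsplit(trimws(readLines(path, warn = FALSE)), "[[:space:]]+")
  tok <- tok[lengths(tok) == 4L]
  labels <- vapply(tok, `[[`, "", 1L)
  pos <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  if (is.null(montage_id))
    montage_id <- if (length(labels) == 21L) "ten20"
                  else if (length(labels) == 289L) "ten5_above_ears"
                  else "custom"
  montage_points(labels, pos, montage_id)
}

## ---- montage computation -------------------------------------------------

check_landmarks_on_surface <- function(mesh, landmarks, tol = 20) {
  d <- closest_point_on_mesh(landmark_matrix(landmarks), mesh)$distance
  if (any(d > tol))
    stop("landmark off surface: ",
         paste(rownames(landmark_matrix(landmarks))[d > tol], collapse = ", "),
         sprintf(" (up to %.1f mm from the mesh)", max(d)), call. = FALSE)
  invisible(TRUE)
}

# Shared curve system: Cz, sagittal and coronal curves, and the ear-level
# ring split into left/right halves from Fpz to Oz.
montage_frame <- function(mesh, landmarks, cz_tol = 0.5) {
  check_landmarks_on_surface(mesh, landmarks)
  czr <- locate_cz(mesh, landmarks, tol = cz_tol)
  sag <- czr$sagittal
  fpz <- fractional_point(sag, 0.10)
  oz <- fractional_point(sag, 0.90)
  t7p <- fractional_point(czr$coronal, 0.10)
  t8p <- fractional_point(czr$coronal, 0.90)
  anchors <- rbind(fpz, t7p, oz, t8p)
  ctr <- colMeans(anchors)
  nrm <- svd(sweep(anchors, 2, ctr))$v[, 3]
  loops <- slice_mesh_plane(mesh, ctr, nrm)
  if (length(loops) == 0L)
    stop("ring plane does not intersect the mesh", call. = FALSE)
  score <- vapply(loops, function(l) {
    o <- loop_as_open(l)
    sum(apply(anchors, 1, function(p) polyline_min_dist(o, p)))
  }, numeric(1))
  ring <- loops[[which.min(score)]]
  if (!ring$closed)
    stop("open surface: the ear-level ring is interrupted", call. = FALSE)
  o <- loop_as_open(ring)
  cum <- polyline_cumlen(o)
  s_fpz <- project_to_polyline(o, fpz)$s
  s_oz <- project_to_polyline(o, oz)$s
  armA <- loop_subpath(o, cum, s_fpz, s_oz)
  armB <- loop_subpath(o, cum, s_oz, s_fpz)
  armB <- armB[rev(seq_len(nrow(armB))), , drop = FALSE]  # also Fpz -> Oz
  dA <- polyline_min_dist(armA, t7p)
  dB <- polyline_min_dist(armB, t7p)
  ring_left <- list(points = if (dA <= dB) armA else armB)
  ring_right <- list(points = if (dA <= dB) armB else armA)
  list(cz = czr$cz, sagittal = sag, coronal = czr$coronal,
       ring_left = ring_left, ring_right = ring_right,
       cz_iterations = czr$iterations)
}

# Positions for a set of (level, column) grid cells. Columns 0..16 span each
# transverse row; column 8 is the midline point itself.
montage_grid_positions <- function(mesh, frame, cells) {
  out <- matrix(NA_real_, nrow(cells), 3L)
  for (f in unique(cells$level)) {
    sel <- cells$level == f
    ks <- cells$column[sel]
    m <- fractional_point(frame$sagittal, f)
    pos <- matrix(NA_real_, length(ks), 3L)
    if (any(ks == 8L)) pos[ks == 8L, ] <- matrix(m, sum(ks == 8L), 3L,
                                                 byrow = TRUE)
    if (any(ks != 8L)) {
      pl <- fractional_point(frame$ring_left, f)
      pr <- fractional_point(frame$ring_right, f)
      row_curve <- geodesic_curve(mesh, pl, pr, m)
      halves <- curve_split(row_curve, m)
      for (i in which(ks != 8L)) {
        k <- ks[i]
        pos[i, ] <- if (k < 8L) fractional_point(halves$first, k / 8)
                    else fractional_point(halves$second, (k - 8L) / 8)
      }
      # pin the midline column exactly to the sagittal point
      pos[ks == 8L, ] <- matrix(m, sum(ks == 8L), 3L, byrow = TRUE)
    }
    out[sel, ] <- pos
  }
  out
}

#' Compute the 10-20 montage on a head surface
#'
#' Places the 21 standard 10-20 electrode sites by plane-slice geodesics
#' anchored at the four cranial landmarks: Cz by alternating sagittal/coronal
#' midpoint iteration, the midline at 10/20% fractions of the nasion-inion
#' curve, the ear-level ring through Fpz/T7/Oz/T8, and the frontal, central
#' and parietal rows at quarter fractions of each half-row.
#'
#' @param mesh a [colored_mesh()] head surface.
#' @param landmarks a [landmark_set()] on (or near) the surface.
#' @param cz_tol Cz convergence tolerance, mm.
#' @return a [montage_points()] set with `montage_id = "ten20"`.
#' @export
compute_1020 <- function(mesh, landmarks, cz_tol = 0.5) {
  frame <- montage_frame(mesh, landmarks, cz_tol)
  cells <- ten20_cells()
  pos <- montage_grid_positions(mesh, frame, cells)
  out <- montage_points(cells$label, pos, "ten20")
  attr(out, "cz_iterations") <- frame$cz_iterations
  out
}

#' Compute the modified 10-5 montage (above-ear subset)
#'
#' Places the 289 sites of the frozen modified 10-5 registry (see
#' [ten5_label_grid()]): 17 midline levels at 5% fractions of the
#' nasion-inion curve by 17 columns per transverse row at eighth fractions of
#' each half-row, all at or above the ear-level ring.
#'
#' @inheritParams compute_1020
#' @return a [montage_points()] set with `montage_id = "ten5_above_ears"`.
#' @export
compute_105_above_ears <- function(mesh, landmarks, cz_tol = 0.5) {
  frame <- montage_frame(mesh, landmarks, cz_tol)
  cells <- ten5_label_grid()
  pos <- montage_grid_positions(mesh, frame, cells)
  out <- montage_points(cells$label, pos, "ten5_above_ears")
  attr(out, "cz_iterations") <- frame$cz_iterations
  out
}

#' Extract the 10-20 subset from a 10-5 montage
#'
#' The 21 standard 10-20 sites are grid cells of the modified 10-5 registry;
#' this pulls them out of an already-computed 10-5 set (identical positions,
#' no recomputation).
#'
#' @param m105 a `ten5_above_ears` [montage_points()] set.
#' @return a `ten20` [montage_points()] set.
#' @export
montage_1020_from_105 <- function(m105) {
  stopifnot(identical(attr(m105, "montage_id"), "ten5_above_ears"))
  cells <- ten20_cells()
  idx <- match(cells$label, m105$label)
  if (anyNA(idx)) stop("10-5 set lacks 10-20 labels", call. = FALSE)
  montage_points(cells$label, as.matrix(m105[idx, c("x", "y", "z")]), "ten20")
}
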