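# Reading and writing colored surface meshes and landmark files.
#
# PLY support covers ascii and binary_little_endian dialects with per-vertex
# color stored either as uchar (0..255, rescaled to [0,1]) or float. OBJ
# colors use the common per-vertex extension "v x y z r g b".

#' Read a colored surface mesh
#'
#' @param path file path.
#' @param format `"ply"` or `"obj"`; guessed from the file extension when
#'   missing.
#' @return a [colored_mesh()].
#' @export
read_colored_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "ply") read_ply(path) else read_obj(path)
}

#' Write a colored surface mesh
#'
#' PLY output is binary_little_endian with double-precision coordinates
#' (round-trip exact) and 8-bit colors (round-trip within 1/255; 0 and 1 map
#' exactly). Use `ascii = TRUE` for a plain-text PLY.
#'
#' @param mesh a [colored_mesh()].
#' @param path output file path.
#' @param format `"ply"` or `"obj"`.
#' @param ascii write ascii PLY instead of binary.
#' @return `path`, invisibly.
#' @export
write_colored_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                               ascii = FALSE) {
  stopifnot(inherits(mesh, "colored_mesh"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (format == "ply") write_ply(mesh, path, ascii = ascii)
  else write_obj(mesh, path)
  invisible(path)
}

## ---- PLY -----------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_column <- function(raw, n, rec_size, offset, type) {
  sz <- ply_type_size[[type]]
  pos <- rep(seq(0L, by = rec_size, length.out = n), each = sz) +
    offset + seq_len(sz)
  what <- if (type %in% c("float", "float32", "double", "float64")) "double"
          else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  out <- readBin(raw[pos], what = what, n = n, size = sz,
                 signed = if (sz < 4) signed else TRUE, endian = "little")
  as.numeric(out)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop("parse error in ", path, ": not a PLY file (missing 'ply' magic)",
         call. = FALSE)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = data.frame)
  cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(ln) == 0L)
      stop("parse error in ", path, ": header ended before end_header",
           call. = FALSE)
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur))
        stop("parse error in ", path, " line ", lineno,
             ": property outside element", call. = FALSE)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt,
         "' (ascii and binary_little_endian are supported)", call. = FALSE)
  ve <- elements[["vertex"]]
  if (is.null(ve)) stop("parse error in ", path, ": no vertex element",
                        call. = FALSE)
  fe <- elements[["face"]]

  if (fmt == "ascii") {
    rest <- readLines(con)
    vlines <- rest[seq_len(ve$count)]
    vtok <- strsplit(trimws(vlines), "[[:space:]]+")
    nnum <- length(ve$props)
    bad <- which(lengths(vtok) < nnum)
    if (length(bad))
      stop("parse error in ", path, " line ", lineno + bad[1],
           ": expected ", nnum, " vertex values", call. = FALSE)
    vm <- matrix(as.numeric(unlist(vtok)), ve$count, nnum, byrow = TRUE)
    colnames(vm) <- vapply(ve$props, `[[`, "", "name")
    fm <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      flines <- rest[ve$count + seq_len(fe$count)]
      ftok <- strsplit(trimws(flines), "[[:space:]]+")
      cnt <- vapply(ftok, function(t) as.integer(t[1]), integer(1))
      if (any(cnt != 3L))
        stop("parse error in ", path, ": non-triangular face (count ",
             cnt[cnt != 3L][1], ")", call. = FALSE)
      fm <- matrix(as.integer(unlist(lapply(ftok, function(t) t[2:4]))),
                   fe$count, 3L, byrow = TRUE)
    }
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    types <- vapply(ve$props, `[[`, "", "type")
    sizes <- ply_type_size[types]
    offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
    rec <- sum(sizes)
    vraw <- raw[seq_len(rec * ve$count)]
    vm <- vapply(seq_along(ve$props), function(j)
      ply_read_column(vraw, ve$count, rec, offs[j], types[j]),
      numeric(ve$count))
    vm <- matrix(vm, ve$count)
    colnames(vm) <- vapply(ve$props, `[[`, "", "name")
    fm <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      fraw <- raw[-seq_len(rec * ve$count)]
      lp <- fe$props[[1]]
      csz <- ply_type_size[[lp$count_type]]
      isz <- ply_type_size[[lp$type]]
      frec <- csz + 3L * isz
      cnt <- ply_read_column(fraw, fe$count, frec, 0L, lp$count_type)
      if (any(cnt != 3))
        stop("parse error in ", path, ": non-triangular face", call. = FALSE)
      fm <- vapply(0:2, function(j)
        ply_read_column(fraw, fe$count, frec, csz + j * isz, lp$type),
        numeric(fe$count))
      fm <- matrix(as.integer(fm), fe$count)
    }
  }

  cn <- colnames(vm)
  if (!all(c("x", "y", "z") %in% cn))
    stop("parse error in ", path, ": vertex element lacks x/y/z", call. = FALSE)
  if (!all(c("red", "green", "blue") %in% cn))
    stop("no per-vertex colors in ", path,
         " (red/green/blue vertex properties required)", call. = FALSE)
  cols <- vm[, c("red", "green", "blue"), drop = FALSE]
  ctype <- vapply(ve$props, `[[`, "", "type")[match("red", cn)]
  if (ctype %in% c("uchar", "uint8", "char", "int8")) cols <- cols / 255
  faces <- if (is.null(fm)) matrix(integer(0), 0L, 3L) else fm + 1L
  colored_mesh(vm[, c("x", "y", "z"), drop = FALSE], faces, cols)
}

write_ply <- function(mesh, path, ascii = FALSE) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  col8 <- as.integer(round(mesh$colors * 255))
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (ascii) "ascii" else "binary_little_endian"),
              "comment produced by scalpmorph",
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "property uchar red", "property uchar green", "property uchar blue",
              sprintf("element face %d", m),
              "property list uchar int vertex_indices",
              "end_header")
  if (ascii) {
    con <- file(path, "wb")  # binary connection: exact \n line endings
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    vl <- sprintf("%.17g %.17g %.17g %d %d %d",
                  mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                  col8[seq_len(n)], col8[n + seq_len(n)], col8[2L * n + seq_len(n)])
    writeLines(vl, con, sep = "\n")
    if (m > 0L) {
      f0 <- mesh$faces - 1L
      writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con, sep = "\n")
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    cmat <- matrix(col8, n, 3L)
    for (i in seq_len(n)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 8, endian = "little")
      writeBin(as.raw(cmat[i, ]), con)
    }
    if (m > 0L) {
      f0 <- mesh$faces - 1L
      for (i in seq_len(m)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
      }
    }
  }
  invisible(path)
}

## ---- OBJ -----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vsel <- grepl("^v\\s", lines)
  fsel <- grepl("^f\\s", lines)
  if (!any(vsel)) stop("parse error in ", path, ": no vertices", call. = FALSE)
  vtok <- strsplit(trimws(sub("^v", "", lines[vsel])), "[[:space:]]+")
  nv <- lengths(vtok)
  if (any(nv < 6L)) {
    bad <- which(vsel)[which(nv < 6L)[1]]
    if (all(nv >= 3L))
      stop("no per-vertex colors in ", path,
           " (expected 'v x y z r g b'; line ", bad, ")", call. = FALSE)
    stop("parse error in ", path, " line ", bad, ": malformed vertex",
         call. = FALSE)
  }
  vm <- matrix(as.numeric(unlist(lapply(vtok, `[`, 1:6))), sum(vsel), 6L,
               byrow = TRUE)
  faces <- matrix(integer(0), 0L, 3L)
  if (any(fsel)) {
    ftok <- strsplit(trimws(sub("^f", "", lines[fsel])), "[[:space:]]+")
    if (any(lengths(ftok) != 3L))
      stop("parse error in ", path, ": only triangular faces are supported",
           call. = FALSE)
    idx <- vapply(ftok, function(t) as.integer(sub("/.*$", "", t)), integer(3))
    faces <- t(idx)
  }
  colored_mesh(vm[, 1:3, drop = FALSE], faces,
               pmin(pmax(vm[, 4:6, drop = FALSE], 0), 1))
}

write_obj <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# produced by scalpmorph", con, sep = "\n")
  writeLines(sprintf("v %.17g %.17g %.17g %.8f %.8f %.8f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                     mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3]),
             con, sep = "\n")
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con, sep = "\n")
  invisible(path)
}

## ---- landmark files ------------------------------------------------------

#' Read a landmark file
#'
#' Plain-text format, one landmark per line: `name x y z` in mm. Names
#' `lpa`/`rpa` are accepted as aliases for the preauricular points.
#'
#' @param path file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
  tok <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(tok) != 4L))
    stop("parse error in ", path, ": expected 'name x y z' per line",
         call. = FALSE)
  nm <- tolower(vapply(tok, `[[`, "", 1L))
  nm[nm == "lpa"] <- "left_preauricular"
  nm[nm == "rpa"] <- "right_preauricular"
  pts <- lapply(tok, function(t) as.numeric(t[2:4]))
  names(pts) <- nm
  need <- c("nasion", "inion", "left_preauricular", "right_preauricular")
  if (!all(need %in% nm))
    stop("landmark file ", path, " must name: ",
         paste(setdiff(need, nm), collapse = ", "), call. = FALSE)
  landmark_set(pts$nasion, pts$inion, pts$left_preauricular,
               pts$right_preauricular)
}

#' Write a landmark file
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  m <- landmark_matrix(landmarks)
  writeLines(sprintf("%s %.6f %.6f %.6f", rownames(m), m[, 1], m[, 2], m[, 3]),
             path)
  invisible(path)
}

## ---- iso-surface from a binary volume ------------------------------------

#' Extract a head surface from a binary volume
#'
#' Triangulates the boundary of the foreground voxel set (cuberille
#' construction: boundary faces between foreground and background voxels,
#' split into oriented triangles), scaled to millimetres. This is the surface
#' step of the MRI-validation pathway, where the anatomical volume has been
#' thresholded to a binary head mask; see [threshold_volume()].
#'
#' @param volume 3D logical (or numeric 0/1) array.
#' @param voxel_size edge length of a voxel in mm (scalar or length-3).
#' @param smooth_iterations Taubin smoothing passes applied to relax the
#'   voxel staircase (approximately volume-preserving; default 0, disabled: the
#    raw cuberille surface has exact voxel-volume semantics).
#' @return a [colored_mesh()] with neutral gray colors. The surface is closed
#'   (every edge shared by exactly two faces) for masks whose foreground does
#'   not touch the volume boundary by more than voxel adjacency.
#' @export
surface_from_binary_mask <- function(volume, voxel_size = 1,
                                     smooth_iterations = 0L) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3D array", call. = FALSE)
  fg <- array(as.logical(volume), dim(volume))
  if (!any(fg)) stop("empty mask: no foreground voxels", call. = FALSE)
  if (all(fg)) stop("all-foreground mask: no boundary inside the volume",
                    call. = FALSE)
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  d <- dim(fg)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq_len(d[ax] - by)
                  idx_src[[ax]] <- seq_len(d[ax] - by) + by }
    else        { idx_dst[[ax]] <- seq_len(d[ax] + by) - by
                  idx_src[[ax]] <- seq_len(d[ax] + by) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  quads <- list()
  # corner offsets per face direction, each 4 x 3, wound so normals point out
  face_def <- list(
    xp = rbind(c(0, -1, -1), c(0, 0, -1), c(0, 0, 0), c(0, -1, 0)),
    xm = rbind(c(-1, -1, -1), c(-1, -1, 0), c(-1, 0, 0), c(-1, 0, -1)),
    yp = rbind(c(-1, 0, -1), c(-1, 0, 0), c(0, 0, 0), c(0, 0, -1)),
    ym = rbind(c(-1, -1, -1), c(0, -1, -1), c(0, -1, 0), c(-1, -1, 0)),
    zp = rbind(c(-1, -1, 0), c(0, -1, 0), c(0, 0, 0), c(-1, 0, 0)),
    zm = rbind(c(-1, -1, -1), c(-1, 0, -1), c(0, 0, -1), c(0, -1, -1)))
  dirs <- list(xp = c(1, 1), xm = c(1, -1), yp = c(2, 1), ym = c(2, -1),
               zp = c(3, 1), zm = c(3, -1))
  for (nm in names(dirs)) {
    ax <- dirs[[nm]][1]; sgn <- dirs[[nm]][2]
    nb <- shift(fg, ax, sgn)
    bnd <- which(fg & !nb, arr.ind = TRUE)
    if (nrow(bnd) == 0L) next
    off <- face_def[[nm]]
    corners <- lapply(1:4, function(ci)
      sweep(bnd, 2, off[ci, ], "+"))
    quads[[nm]] <- corners
  }
  # corner (i,j,k) are integer triples in 0..d; linear ids for dedup
  key <- function(m) m[, 1] + (d[1] + 1) * (m[, 2] + (d[2] + 1) * m[, 3])
  all_corners <- do.call(rbind, lapply(quads, function(q) do.call(rbind, q)))
  ids <- key(all_corners)
  uids <- sort(unique(ids))
  lookup <- function(m) match(key(m), uids)
  verts <- cbind(uids %% (d[1] + 1),
                 (uids %/% (d[1] + 1)) %% (d[2] + 1),
                 uids %/% ((d[1] + 1) * (d[2] + 1)))
  verts <- sweep(verts, 2, voxel_size, "*")
  faces <- do.call(rbind, lapply(quads, function(q) {
    i1 <- lookup(q[[1]]); i2 <- lookup(q[[2]])
    i3 <- lookup(q[[3]]); i4 <- lookup(q[[4]])
    rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
  }))
  out <- colored_mesh(verts, faces, c(0.7, 0.7, 0.7))
  if (smooth_iterations > 0L) out <- taubin_smooth(out, smooth_iterations)
  out
}

#' Taubin mesh smoothing
#'
#' Alternating shrink/inflate Laplacian passes (`lambda`/`mu` scheme) with
#' uniform weights: smooths the voxel staircase of extracted iso-surfaces
#' while approximately preserving volume.
#'
#' @param mesh a [colored_mesh()].
#' @param iterations number of lambda+mu pass pairs.
#' @param lambda,mu Taubin coefficients (defaults 0.5 / -0.53).
#' @return the smoothed [colored_mesh()].
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  e <- mesh_edges(mesh$faces)
  e <- unique(rbind(e, e[, 2:1]))
  deg <- tabulate(e[, 1], nrow(mesh$vertices))
  v <- mesh$vertices
  lap_step <- function(v, w) {
    nb <- rowsum(v[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
    v + w * (nb / deg - v)
  }
  for (i in seq_len(iterations)) {
    v <- lap_step(v, lambda)
    v <- lap_step(v, mu)
  }
  mesh$vertices <- v
  mesh
}

#' Normalized thresholding of an intensity volume
#'
#' Scales intensities to `[0, 1]` by the 99.9th percentile, thresholds at
#' `level`, keeps the largest 6-connected foreground component and fills
#' internal background holes (background components not connected to the
#' volume border). The result is a binary head mask suitable for
#' [surface_from_binary_mask()].
#'
#' @param volume 3D numeric array of intensities.
#' @param level threshold on the normalized intensity scale (default 0.1).
#' @return 3D logical array.
#' @export
threshold_volume <- function(volume, level = 0.1) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3D array", call. = FALSE)
  hi <- stats::quantile(volume, 0.999, names = FALSE)
  if (hi <= 0) stop("volume has no positive intensities", call. = FALSE)
  fg <- (volume / hi) >= level
  if (!any(fg)) stop("empty mask after thresholding", call. = FALSE)
  lab <- label_components(fg)
  keep <- which.max(tabulate(lab[lab > 0L]))
  fg <- lab == keep
  # fill holes: background components that never touch the border
  bglab <- label_components(!fg)
  d <- dim(fg)
  border_ids <- unique(c(bglab[c(1, d[1]), , ], bglab[, c(1, d[2]), ],
                         bglab[, , c(1, d[3])]))
  border_ids <- border_ids[border_ids > 0L]
  fg | (bglab > 0L & !(bglab %in% border_ids))
}

# 6-connected component labelling by repeated neighbour-label propagation.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  shift_lab <- function(arr, ax, by) {
    out <- array(0L, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq_len(d[ax] - by)
                  idx_src[[ax]] <- seq_len(d[ax] - by) + by }
    else        { idx_dst[[ax]] <- seq_len(d[ax] + by) - by
                  idx_src[[ax]] <- seq_len(d[ax] + by) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  repeat {
    new <- lab
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      nb <- shift_lab(new, ax, by)
      upd <- mask & nb > 0L & (new == 0L | nb < new)
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}
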