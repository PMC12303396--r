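# Fiducial isolation: color/saturation/hue filtering of scan vertices and
# partitioning of the surviving points into per-module clusters.

#' Color filter specification
#'
#' Thresholds used to isolate the red fiducial triangles from skin, hair and
#' the black module bodies: normalized red channel >= `red_min`, HSV
#' saturation >= `sat_min`, and hue within `hue_max` of the red origin of the
#' `[0, 1)` hue circle. Because red straddles the hue origin, the hue test is
#' satisfied by `hue <= hue_max` or `hue >= 1 - hue_max`.
#'
#' @param red_min minimum normalized red channel (default 0.5).
#' @param sat_min minimum saturation (default 0.7).
#' @param hue_max maximum hue distance from red, on a `[0, 1]` circle
#'   (default 0.1).
#' @return An object of class `color_filter_spec`.
#' @export
color_filter_spec <- function(red_min = 0.5, sat_min = 0.7, hue_max = 0.1) {
  v <- c(red_min = red_min, sat_min = sat_min, hue_max = hue_max)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("all color filter thresholds must lie in [0, 1]", call. = FALSE)
  structure(as.list(v), class = "color_filter_spec")
}

#' Select fiducial vertices by color
#'
#' Applies the red/saturation/hue filter to the per-vertex colors of a scan.
#' Hue and saturation follow the standard hexcone HSV model (hue in `[0, 1)`),
#' the red channel is the normalized channel value itself.
#'
#' @param mesh a [colored_mesh()] with per-vertex color.
#' @param spec a [color_filter_spec()].
#' @return integer vector of vertex indices passing the filter (possibly
#'   empty).
#' @export
filter_fiducial_vertices <- function(mesh, spec = color_filter_spec()) {
  stopifnot(inherits(mesh, "colored_mesh"), inherits(spec, "color_filter_spec"))
  hsv <- grDevices::rgb2hsv(t(mesh$colors), maxColorValue = 1)
  h <- hsv[1, ]; s <- hsv[2, ]
  r <- mesh$colors[, 1]
  pass <- r >= spec$red_min & s >= spec$sat_min &
    (h <= spec$hue_max | h >= 1 - spec$hue_max)
  which(pass)
}

#' A fiducial cluster
#'
#' One detected module fiducial: the member vertex indices, their 3D
#' coordinates, and the centroid. Constructed by [cluster_fiducials()].
#'
#' @param member_indices integer vertex indices into the source scan.
#' @param points member coordinates, one row per member (mm).
#' @return object of class `fiducial_cluster` with elements `member_indices`,
#'   `points`, `centroid`, `diameter`.
#' @export
fiducial_cluster <- function(member_indices, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 3L)
    stop("a fiducial cluster needs at least 3 members", call. = FALSE)
  structure(list(member_indices = as.integer(member_indices),
                 points = points,
                 centroid = colMeans(points),
                 diameter = max(stats::dist(points))),
            class = "fiducial_cluster")
}

#' @export
print.fiducial_cluster <- function(x, ...) {
  cat(sprintf("<fiducial_cluster> %d members, diameter %.1f mm, centroid (%.1f, %.1f, %.1f)\n",
              nrow(x$points), x$diameter, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# Seeded k-means++ initial centers.
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(points, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    centers[j, ] <- points[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(points, 2, centers[j, ])^2))
  }
  centers
}

#' Partition filtered fiducial points into per-module clusters
#'
#' k-means clustering (seeded k-means++ initialization, Lloyd iterations) of
#' the color-filtered vertices into `k` clusters, one per photogrammetric
#' module, subject to the physical constraint that all members of a cluster
#' lie within `diameter_bound` of each other. Restarts with fresh seeds when a
#' converged partition violates the bound or produces a cluster with fewer
#' than 3 members, and fails after `restarts` attempts.
#'
#' @param points n x 3 matrix of filtered vertex coordinates (mm).
#' @param k expected number of modules (default 17).
#' @param diameter_bound maximum pairwise within-cluster distance in mm
#'   (default 50).
#' @param seed integer seed making the partition deterministic.
#' @param restarts restart budget (default 10).
#' @param member_indices optional vertex indices carried through to the
#'   clusters (defaults to row numbers).
#' @return list of `k` [fiducial_cluster()] objects, ordered by decreasing
#'   member count.
#' @export
cluster_fiducials <- function(points, k = 17L, diameter_bound = 50,
                              seed = 1L, restarts = 10L,
                              member_indices = NULL) {
  points <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(points)
  if (n == 0L) stop("no points to cluster", call. = FALSE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (n < k) stop("too few points: ", n, " points for k = ", k, call. = FALSE)
  if (is.null(member_indices)) member_indices <- seq_len(n)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  for (attempt in seq_len(restarts)) {
    centers <- kmeanspp_centers(points, k)
    km <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"))
    sizes <- tabulate(km$cluster, k)
    if (any(sizes < 3L)) next
    cl <- lapply(seq_len(k), function(j) {
      sel <- km$cluster == j
      fiducial_cluster(member_indices[sel], points[sel, , drop = FALSE])
    })
    if (all(vapply(cl, `[[`, 0, "diameter") <= diameter_bound))
      return(cl[order(-sizes)])
  }
  stop("no ", k, "-cluster partition within the ", diameter_bound,
       " mm diameter bound found after ", restarts, " restarts", call. = FALSE)
}
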