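# Colored mesh containers, PLY/OBJ round trips, landmark files, and the
# binary-mask iso-surface.

test_that("colored_mesh enforces its invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(colored_mesh(v, rbind(c(1, 2, 3)), c(1, 0, 0)),
                  "colored_mesh")
  expect_error(colored_mesh(v, rbind(c(1, 2, 4)), c(1, 0, 0)), "face indices")
  expect_error(colored_mesh(v, rbind(c(1, 2, 3)), c(1.2, 0, 0)), "\\[0, 1\\]")
  expect_error(colored_mesh(v[1:2, ], rbind(c(1, 2, 1)), c(1, 0, 0)),
               "at least 3 vertices")
  # point cloud (no faces) is allowed
  pc <- colored_mesh(v, NULL, c(0, 1, 0))
  expect_equal(nrow(pc$faces), 0L)
})

test_that("8-bit PLY colors are rescaled to [0,1] on read", {
  m <- tetra_mesh(c(1, 0, 0))
  p <- withr::local_tempfile(fileext = ".ply")
  write_colored_mesh(m, p)          # writes uchar colors
  r <- read_colored_mesh(p)
  expect_equal(r$colors, m$colors)  # 255 -> 1, 0 -> 0 exactly
})

test_that("binary PLY round trip is exact in coordinates, 1/255 in color", {
  set.seed(42)
  v <- matrix(rnorm(30, sd = 50), 10, 3)
  cols <- matrix(runif(30), 10, 3)
  m <- colored_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)), cols)
  p <- withr::local_tempfile(fileext = ".ply")
  write_colored_mesh(m, p)
  r <- read_colored_mesh(p)
  expect_identical(r$vertices, m$vertices)     # bit-for-bit (double props)
  expect_identical(r$faces, m$faces)
  expect_lt(max(abs(r$colors - m$colors)), 1 / 255)
})

test_that("ascii PLY and OBJ round trips preserve the mesh", {
  m <- tetra_mesh(c(0.3, 0.9, 0.2))
  for (args in list(list(fileext = ".ply", ascii = TRUE),
                    list(fileext = ".obj", ascii = FALSE))) {
    p <- withr::local_tempfile(fileext = args$fileext)
    write_colored_mesh(m, p, ascii = args$ascii)
    r <- read_colored_mesh(p)
    expect_equal(r$vertices, m$vertices, tolerance = 1e-9)
    expect_identical(r$faces, m$faces)
    expect_lt(max(abs(r$colors - m$colors)), 1 / 255)
  }
})

test_that("a point cloud writes to a valid PLY with zero faces", {
  m <- colored_mesh(matrix(rnorm(9), 3, 3), NULL, c(0.5, 0.5, 0.5))
  p <- withr::local_tempfile(fileext = ".ply")
  write_colored_mesh(m, p)
  r <- read_colored_mesh(p)
  expect_equal(nrow(r$faces), 0L)
  expect_equal(r$vertices, m$vertices)
})

test_that("missing colors and malformed files raise parse errors", {
  p <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0"), p)
  expect_error(read_colored_mesh(p), "no per-vertex colors")
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not a ply", "garbage"), p2)
  expect_error(read_colored_mesh(p2), "parse error")
  p3 <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p3)
  expect_error(read_colored_mesh(p3), "no per-vertex colors")
})

test_that("phantom scan survives a write/read cycle with declared counts", {
  ph <- default_cap_phantom()
  p <- withr::local_tempfile(fileext = ".ply")
  write_colored_mesh(ph$scan, p)
  r <- read_colored_mesh(p)
  expect_identical(nrow(r$vertices), nrow(ph$scan$vertices))
  expect_identical(nrow(r$faces), nrow(ph$scan$faces))
  expect_identical(r$vertices, ph$scan$vertices)
})

test_that("landmark files round trip and validate", {
  lm <- landmark_set(c(0, 100, 0), c(0, -100, 0), c(-95, 10, -5),
                     c(95, 10, -5))
  p <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(lm, p)
  r <- read_landmarks(p)
  expect_equal(landmark_matrix(r), landmark_matrix(lm), tolerance = 1e-6)
  expect_error(landmark_set(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "distinct")
  expect_error(landmark_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "collinear")
})

test_that("iso-surface of a spherical mask is closed with correct volume", {
  d <- 45L
  ctr <- c(23, 23, 23)
  g <- expand.grid(i = 1:d, j = 1:d, k = 1:d)
  vol <- array((g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2 <= 400,
               c(d, d, d))
  m <- surface_from_binary_mask(vol, 1)
  expect_true(is_closed_mesh(m))
  r <- sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))
  # cuberille staircase: voxel-corner vertices stay within one voxel
  # diagonal of the digitised boundary
  expect_true(all(abs(r - 20) < 1.8))
  expect_lt(mean(abs(r - 20)), 0.6)
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3),
            0.005)
})

test_that("iso-surface of a single voxel is a closed 1 mm^3 surface", {
  vol <- array(FALSE, c(3, 3, 3)); vol[2, 2, 2] <- TRUE
  m <- surface_from_binary_mask(vol, 1)
  expect_true(is_closed_mesh(m))
  expect_equal(mesh_volume(m), 1)
  # voxel size scales coordinates
  m2 <- surface_from_binary_mask(vol, 2)
  expect_equal(mesh_volume(m2), 8)
})

test_that("degenerate masks are rejected", {
  expect_error(surface_from_binary_mask(array(FALSE, c(3, 3, 3))),
               "empty mask")
  expect_error(surface_from_binary_mask(array(TRUE, c(3, 3, 3))),
               "all-foreground")
})

test_that("normalized thresholding keeps the main component and fills holes", {
  d <- 21L
  g <- expand.grid(i = 1:d, j = 1:d, k = 1:d)
  r2 <- (g$i - 11)^2 + (g$j - 11)^2 + (g$k - 11)^2
  vol <- array(0, c(d, d, d))
  vol[r2 <= 64] <- 100           # head
  vol[r2 <= 4] <- 0              # interior cavity, should be filled
  vol[2, 2, 2] <- 100            # disconnected speck, should be dropped
  mask <- threshold_volume(vol, level = 0.1)
  expect_false(mask[2, 2, 2])
  expect_true(mask[11, 11, 11])  # hole filled
  expect_true(mask[11, 11, 16])
  expect_false(mask[1, 1, 11])
})
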