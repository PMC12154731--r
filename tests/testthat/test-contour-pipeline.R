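test_that("a spherical Gaussian yields one closed zero contour at the predicted radius", {
  beta <- 2          # single s with alpha = 1 gives rho ~ exp(-2 r^2)
  w <- single_s_wavefunction(alpha = 1)
  dummy <- wavefunction(data.frame(element = c("C", "O", "O"), index = 1:3,
                                   x = c(0, 1.5, 0), y = c(0, 0, 2),
                                   z = c(0, 0, 0)),
                        list(basis_shell(1L, "s", 1, 1)), matrix(1, 1, 1), 2)
  plane <- plane_from_atoms(dummy, 1, 2, 3, padding = 2, resolution = 10)
  map <- sample_map(w, plane, "laplacian")
  ct <- zero_contour(map)
  # contours away from the grid border: a single closed ring
  interior <- Filter(function(p) all(abs(p) < plane$extent_u - 0.2),
                     ct$polylines)
  expect_equal(length(interior), 1L)
  radii <- sqrt(rowSums(interior[[1]]^2))
  r0 <- sqrt(3 / (2 * beta))
  spacing <- 2 * plane$extent_u / (plane$n_u - 1)
  expect_true(all(abs(radii - r0) < spacing))
})

test_that("zero_contour rejects density maps and returns empty sets for signed fields", {
  const_map <- synthetic_map(function(u, v) 1 + 0 * u)
  expect_length(zero_contour(const_map)$polylines, 0L)
  dmap <- const_map
  dmap$field_kind <- "density"
  expect_error(zero_contour(dmap), class = "lapnet_contract")
})

test_that("every sign-changing grid edge is crossed by the contour, and only those", {
  set.seed(8)
  n <- 15
  vals <- matrix(sample(c(-1.3, -0.4, 0.6, 1.1), n * n, replace = TRUE), n, n)
  map <- synthetic_map(function(u, v) 0 * u)
  map$plane$n_u <- n; map$plane$n_v <- n
  map$values <- vals
  g <- grid_coords(map$plane)
  ct <- zero_contour(map)
  verts <- do.call(rbind, ct$polylines)
  spacing <- g$u[2] - g$u[1]
  # brute-force edge scan: horizontal and vertical neighbor pairs
  crossed_u <- which(vals[-n, ] * vals[-1, ] < 0, arr.ind = TRUE)  # along u
  crossed_v <- which(vals[, -n] * vals[, -1] < 0, arr.ind = TRUE)  # along v
  on_edge_u <- function(i, j) {
    any(abs(verts[, 2] - g$v[j]) < 1e-9 &
          verts[, 1] > g$u[i] - 1e-9 & verts[, 1] < g$u[i + 1] + 1e-9)
  }
  on_edge_v <- function(i, j) {
    any(abs(verts[, 1] - g$u[i]) < 1e-9 &
          verts[, 2] > g$v[j] - 1e-9 & verts[, 2] < g$v[j + 1] + 1e-9)
  }
  expect_true(all(apply(crossed_u, 1, function(e) on_edge_u(e[1], e[2]))))
  expect_true(all(apply(crossed_v, 1, function(e) on_edge_v(e[1], e[2]))))
  # vertices interpolate to zero: |bilinear value| below 1e-6 x field range
  fv <- bilinear_interp(g$u, g$v, vals, verts[, 1], verts[, 2])
  expect_true(all(abs(fv) < 1e-6 * diff(range(vals))))
})

test_that("contour vertices of a physical map interpolate to zero field", {
  map <- frame_map(0.2, resolution = 10)
  ct <- zero_contour(map)
  g <- grid_coords(map$plane)
  verts <- do.call(rbind, ct$polylines)
  fv <- bilinear_interp(g$u, g$v, map$values, verts[, 1], verts[, 2])
  expect_true(all(abs(fv) < 1e-6 * diff(range(map$values)), na.rm = TRUE))
})

test_that("rendering is 960 x 720, deterministic, and blank for empty contours", {
  map <- frame_map(0, resolution = 8)
  ct <- zero_contour(map)
  img1 <- render_map(ct, map)
  img2 <- render_map(ct, map)
  expect_equal(img1$width, 960L)
  expect_equal(img1$height, 720L)
  expect_identical(img1$pixels, img2$pixels)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_rendered_png(img1, f1)
  write_rendered_png(img2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # empty contour set, no fill, no marks: a uniform background canvas
  style <- render_style(fill = FALSE, line = TRUE, atom_marks = FALSE)
  blank <- render_map(structure(list(polylines = list(), closed = logical(0)),
                                class = "contour_set"), map, style)
  expect_equal(dim(blank$pixels), c(720L, 960L))
  expect_true(all(blank$pixels == style$pos_shade))
})

test_that("a drawn circle rasterizes with its centroid at the mapped center", {
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- cbind(u = 0.8 * cos(th) + 0.3, v = 0.8 * sin(th) - 0.4)
  ct <- structure(list(polylines = list(circ), closed = TRUE),
                  class = "contour_set")
  map <- synthetic_map(function(u, v) 1 + 0 * u)
  img <- render_map(ct, map, render_style(fill = FALSE, atom_marks = FALSE))
  drawn <- which(img$pixels < 0.5, arr.ind = TRUE)
  center_px <- c((0.3 + 6) * 60 + 0.5, (-0.4 + 6) * 60 + 0.5)
  expect_lt(abs(mean(drawn[, 1]) - center_px[1]), 1)
  expect_lt(abs(mean(drawn[, 2]) - center_px[2]), 1)
})

test_that("the carbonyl crop is 550 x 720, keeps C and O, and excludes the nucleophile", {
  map <- frame_map(0.15, resolution = 8)
  full <- render_map(zero_contour(map), map)
  crp <- crop_carbonyl(full, map)
  expect_equal(crp$width, 550L)
  expect_equal(crp$height, 720L)
  expect_equal(dim(crp$pixels), c(720L, 550L))
  # nucleophile mark column falls outside the crop window
  nu_col <- (map$atom_marks$v[3] + 6) * 60 + 0.5
  left <- crp$provenance$crop_left
  expect_true(nu_col < left || nu_col > left + 549)
  # C and O inside
  for (i in 1:2) {
    col <- (map$atom_marks$v[i] + 6) * 60 + 0.5
    expect_true(col >= left && col <= left + 549)
  }
  expect_error(crop_carbonyl(crp, map), class = "lapnet_crop")
})

test_that("rigidly transformed geometry renders to the identical cropped image", {
  geom <- carbonyl_geometry()
  theta <- -0.9
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3)
  geom2 <- geom
  xyz <- as.matrix(geom$atoms[, c("x", "y", "z")]) %*% t(R)
  geom2$atoms$x <- xyz[, 1] + 0.7
  geom2$atoms$y <- xyz[, 2] - 1.1
  geom2$atoms$z <- xyz[, 3] + 2.2
  crop_of <- function(g) {
    map <- frame_map(0.2, resolution = 8, geometry = g)
    crop_carbonyl(render_map(zero_contour(map), map), map)$pixels
  }
  expect_identical(crop_of(geom), crop_of(geom2))
})

test_that("downscaling block-averages and checks divisibility", {
  m <- matrix(seq_len(16) / 16, 4, 4)
  d <- downscale_image(m, 2)
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(d[1, 1], mean(m[1:2, 1:2]))
  expect_error(downscale_image(m, 3), class = "lapnet_validation")
})
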