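test_that("single-Gaussian closed forms are reproduced to 1e-10", {
  alpha <- 1
  w <- single_s_wavefunction(alpha = alpha, occ = 2)
  rho0 <- 2 * (2 * alpha / pi)^1.5
  expect_equal(evaluate_density(w, c(0, 0, 0)), rho0, tolerance = 1e-10)
  expect_equal(evaluate_density(w, c(1, 0, 0)), rho0 * exp(-2 * alpha),
               tolerance = 1e-10)
  # rho = A exp(-beta r^2) with beta = 2 alpha: lap rho(0) = -6 beta A,
  # and lap rho = 0 at r^2 = 3 / (2 beta)
  beta <- 2 * alpha
  expect_equal(evaluate_laplacian(w, c(0, 0, 0)), -6 * beta * rho0,
               tolerance = 1e-10)
  r0 <- sqrt(3 / (2 * beta))
  expect_equal(evaluate_laplacian(w, c(r0, 0, 0)) / (6 * beta * rho0), 0,
               tolerance = 1e-10)
  expect_true(all(evaluate_density(w, matrix(rnorm(30), 10, 3)) >= 0))
})

test_that("analytic Laplacian matches the finite-difference oracle on random wavefunctions", {
  for (seed in c(2, 5)) {
    w <- random_wavefunction(seed)
    set.seed(seed + 100)
    pts <- matrix(runif(150, -2.5, 2.5), 50, 3)
    # exclude near-nuclear points where finite differences are ill-conditioned
    nuc <- as.matrix(w$atoms[, c("x", "y", "z")])
    dmin <- apply(pts, 1, function(p) min(sqrt(colSums((t(nuc) - p)^2))))
    pts <- pts[dmin > 0.05, , drop = FALSE]
    a <- evaluate_laplacian(w, pts)
    fd <- fd_laplacian(w, pts)
    scale <- max(abs(a))
    expect_true(all(abs(a - fd) <= 1e-5 * pmax(abs(a), 1e-6 * scale)))
  }
})

test_that("the density integrates to the electron count", {
  w <- formaldehyde_promolecule()
  g <- seq(-6.5, 7.5, by = 0.15)
  pts <- as.matrix(expand.grid(x = g, y = g, z = seq(-6.5, 6.5, by = 0.15)))
  rho <- evaluate_density(w, pts)
  expect_equal(sum(rho) * 0.15^3, 16, tolerance = 1e-3)
})

test_that("plane construction is canonical and covers the atoms", {
  geom <- carbonyl_geometry()
  wfn <- make_promolecule(geom, 0)
  plane <- plane_from_atoms(wfn, 1, 2, 5)
  # origin at C, u toward O, Nu at non-negative v
  expect_equal(plane$origin, unname(unlist(geom$atoms[1, c("x", "y", "z")])))
  d_co <- sqrt(sum((geom$atoms[2, c("x", "y", "z")] -
                      geom$atoms[1, c("x", "y", "z")])^2))
  expect_equal(plane$atom_marks$u, c(0, d_co, plane$atom_marks$u[3]),
               tolerance = 1e-10)
  expect_true(plane$atom_marks$v[3] >= 0)
  # all three atoms lie in the plane to 1e-10
  for (i in c(1, 2, 5)) {
    p <- unlist(geom$atoms[i, c("x", "y", "z")]) - plane$origin
    off <- p - sum(p * plane$axis_u) * plane$axis_u -
      sum(p * plane$axis_v) * plane$axis_v
    expect_lt(sqrt(sum(off^2)), 1e-10)
  }
  # extents cover atoms plus padding
  expect_gte(plane$extent_u, max(abs(plane$atom_marks$u)) + 4 - 1e-9)
  expect_gte(plane$extent_v, max(abs(plane$atom_marks$v)) + 4 - 1e-9)
  # canonical xy-plane example
  w2 <- wavefunction(data.frame(element = c("C", "O", "O"), index = 1:3,
                                x = c(0, 2.3, 0), y = c(0, 0, 5.4),
                                z = c(0, 0, 0)),
                     list(basis_shell(1L, "s", 1, 1)), matrix(1, 1, 1), 2)
  p2 <- plane_from_atoms(w2, 1, 2, 3)
  expect_equal(p2$axis_u, c(1, 0, 0))
  expect_equal(p2$axis_v, c(0, 1, 0))
})

test_that("rigid rotation + translation leaves the map invariant", {
  geom <- carbonyl_geometry()
  theta <- 0.7; phi <- 1.2
  Rz <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(phi), sin(phi), 0, -sin(phi), cos(phi)), 3, 3)
  R <- Rx %*% Rz
  shift <- c(1.5, -2, 0.8)
  geom2 <- geom
  xyz <- as.matrix(geom$atoms[, c("x", "y", "z")]) %*% t(R)
  geom2$atoms$x <- xyz[, 1] + shift[1]
  geom2$atoms$y <- xyz[, 2] + shift[2]
  geom2$atoms$z <- xyz[, 3] + shift[3]
  m1 <- frame_map(0.15, resolution = 6, geometry = geom)
  m2 <- frame_map(0.15, resolution = 6, geometry = geom2)
  expect_equal(m1$atom_marks$u, m2$atom_marks$u, tolerance = 1e-8)
  expect_equal(m1$atom_marks$v, m2$atom_marks$v, tolerance = 1e-8)
  expect_equal(m1$values, m2$values, tolerance = 1e-8)
})

test_that("degenerate plane geometries raise geometry errors", {
  w <- wavefunction(data.frame(element = c("C", "O", "O"), index = 1:3,
                               x = c(0, 1, 2), y = c(0, 0, 0), z = c(0, 0, 0)),
                    list(basis_shell(1L, "s", 1, 1)), matrix(1, 1, 1), 2)
  expect_error(plane_from_atoms(w, 1, 2, 3), class = "lapnet_geometry")
  expect_error(plane_from_atoms(w, 1, 1, 3), class = "lapnet_geometry")
  expect_error(plane_from_atoms(w, 1, 2, 9), class = "lapnet_geometry")
})

test_that("sampled maps agree with pointwise evaluation and symmetry", {
  w <- single_s_wavefunction()
  dummy <- wavefunction(data.frame(element = c("C", "O", "O"), index = 1:3,
                                   x = c(0, 1.5, 0), y = c(0, 0, 2),
                                   z = c(0, 0, 0)),
                        list(basis_shell(1L, "s", 1, 1)), matrix(1, 1, 1), 2)
  plane <- plane_from_atoms(dummy, 1, 2, 3, padding = 2, resolution = 5)
  map <- sample_map(w, plane, "density")
  # spherical density centered at the origin: (u,v) -> (-u,-v) symmetry
  expect_equal(map$values, map$values[rev(seq_len(nrow(map$values))),
                                      rev(seq_len(ncol(map$values)))],
               tolerance = 1e-10)
  # values equal direct pointwise calls
  g <- grid_coords(plane)
  i <- c(1, 5, 11); j <- c(2, 8, 17)
  pts <- cbind(g$u[i], g$v[j], 0)
  expect_equal(map$values[cbind(i, j)], evaluate_density(w, pts))
  # Laplacian sign changes exactly once along a ray from the center
  lmap <- sample_map(w, plane, "laplacian")
  mid_v <- which.min(abs(g$v))
  ray <- lmap$values[g$u >= 0, mid_v]
  expect_equal(sum(diff(sign(ray)) != 0), 1L)
})

test_that("map text export writes a readable matrix", {
  map <- frame_map(0, resolution = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  export_map_text(map, path)
  vals <- as.matrix(utils::read.table(path, comment.char = "#"))
  expect_equal(dim(vals), dim(map$values))
  expect_equal(unname(vals[3, 4]), map$values[3, 4], tolerance = 1e-12)
})
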