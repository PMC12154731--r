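# Shared fixtures, built in code.

extdata <- function(f) system.file("extdata", f, package = "lapnet")

# single normalized s Gaussian, one MO
single_s_wavefunction <- function(alpha = 1, occ = 2) {
  wavefunction(data.frame(element = "H", index = 1L, x = 0, y = 0, z = 0),
               list(basis_shell(1L, "s", alpha, 1)),
               matrix(1, 1, 1), occ)
}

# formaldehyde-like synthetic promolecule (C, O, 2 H), no nucleophile
formaldehyde_promolecule <- function() {
  g <- carbonyl_geometry()
  g$atoms <- g$atoms[1:4, ]
  g$nu_idx <- NULL
  make_promolecule(g, 0)
}

# full 5-atom frame wavefunction + its Laplacian map
frame_map <- function(lobe = 0, resolution = 10, geometry = carbonyl_geometry()) {
  wfn <- make_promolecule(geometry, lobe)
  plane <- plane_from_atoms(wfn, geometry$c_idx, geometry$o_idx,
                            geometry$nu_idx, resolution = resolution)
  sample_map(wfn, plane, "laplacian")
}

# randomized small s/p/d wavefunction for derivative oracles
random_wavefunction <- function(seed) {
  set.seed(seed)
  n_atoms <- sample(2:3, 1)
  atoms <- data.frame(element = sample(c("C", "O", "N"), n_atoms, replace = TRUE),
                      index = seq_len(n_atoms),
                      x = rnorm(n_atoms), y = rnorm(n_atoms), z = rnorm(n_atoms))
  shells <- list()
  for (i in seq_len(n_atoms)) {
    shells <- c(shells,
                list(basis_shell(i, "s", runif(2, 0.3, 3), runif(2, 0.3, 1)),
                     basis_shell(i, "p", runif(1, 0.3, 2), 1)))
  }
  shells <- c(shells, list(basis_shell(1L, "d", runif(1, 0.4, 1.5), 1)))
  nb <- sum(vapply(shells, function(s) switch(s$l, s = 1L, p = 3L, d = 6L),
                   integer(1)))
  n_mo <- 4L
  C <- matrix(rnorm(n_mo * nb, 0, 0.4), n_mo, nb)
  wavefunction(atoms, shells, C, rep(2, n_mo))
}

# 5-point central finite-difference Laplacian of the analytic density
fd_laplacian <- function(wfn, pts, h = 1e-3) {
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    total <- 0
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- 1
      f <- evaluate_density(wfn, rbind(p + 2 * h * e, p + h * e, p,
                                       p - h * e, p - 2 * h * e))
      total <- total + (-f[1] + 16 * f[2] - 30 * f[3] + 16 * f[4] - f[5]) /
        (12 * h^2)
    }
    total
  }, numeric(1))
}

# scalar_field_map with prescribed values on a frame-derived plane
synthetic_map <- function(values_fn, n = 41, extent = 2) {
  u <- seq(-extent, extent, length.out = n)
  plane <- structure(list(origin = c(0, 0, 0), axis_u = c(1, 0, 0),
                          axis_v = c(0, 1, 0), extent_u = extent,
                          extent_v = extent, n_u = n, n_v = n,
                          atom_marks = data.frame(atom = c("C", "O", "Nu"),
                                                  u = c(0, 1, -0.5),
                                                  v = c(0, 0, 1.5))),
                     class = "grid_plane")
  vals <- outer(u, u, values_fn)
  structure(list(plane = plane, values = vals, field_kind = "laplacian",
                 atom_marks = plane$atom_marks),
            class = "scalar_field_map")
}

# lazily built shared small datasets (built once per test run)
.lapnet_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .lapnet_cache))
    assign(key, force(expr), envir = .lapnet_cache)
  get(key, envir = .lapnet_cache)
}

small_graphical_dataset <- function() {
  cached("graph60", generate_dataset(synthetic_spec(n_images = 60, seed = 3,
                                                    tier = "graphical")))
}
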