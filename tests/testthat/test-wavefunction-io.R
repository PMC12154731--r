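test_that("a minimal one-atom Molden file parses to a 2-electron wavefunction", {
  w <- read_molden(extdata("h_atom.molden"))
  expect_s3_class(w, "wavefunction")
  expect_equal(nrow(w$atoms), 1L)
  expect_equal(electron_count(w), 2)
  expect_equal(ncol(w$mo_coefficients), 1L)
})

test_that("write/read round-trips are field-wise identical", {
  for (seed in c(1, 7, 23)) {
    w <- random_wavefunction(seed)
    path <- withr::local_tempfile(fileext = ".molden")
    write_molden(w, path)
    w2 <- read_molden(path)
    expect_equal(w2$atoms$element, w$atoms$element)
    expect_equal(as.matrix(w2$atoms[, c("x", "y", "z")]),
                 as.matrix(w$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-10)
    expect_equal(w2$mo_coefficients, w$mo_coefficients, tolerance = 1e-10)
    expect_equal(w2$occupations, w$occupations, tolerance = 1e-10)
    for (k in seq_along(w$shells)) {
      expect_equal(w2$shells[[k]]$exponents, w$shells[[k]]$exponents,
                   tolerance = 1e-10)
      expect_equal(w2$shells[[k]]$coefficients, w$shells[[k]]$coefficients,
                   tolerance = 1e-10)
    }
  }
  w <- formaldehyde_promolecule()
  path <- withr::local_tempfile(fileext = ".molden")
  write_molden(w, path)
  expect_equal(electron_count(read_molden(path)), 16)
})

test_that("unsupported and malformed files are rejected with named errors", {
  path <- withr::local_tempfile(fileext = ".molden")
  writeLines(c("[Molden Format]", "[Atoms] AU", "H 1 1 0 0 0", "[GTO]",
               "1 0", " g 1 1.00", "  1.0 1.0", "", "[MO]",
               " Occup= 2", "  1 1.0"), path)
  expect_error(read_molden(path), class = "lapnet_unsupported")

  # MO coefficient row length disagreeing with the expanded basis dimension
  path2 <- withr::local_tempfile(fileext = ".molden")
  writeLines(c("[Molden Format]", "[Atoms] AU", "H 1 1 0 0 0", "[GTO]",
               "1 0", " s 1 1.00", "  1.0 1.0", "", "[MO]",
               " Occup= 2", "  1 1.0", "  2 0.5"), path2)
  expect_error(read_molden(path2), class = "lapnet_parse")

  path3 <- withr::local_tempfile(fileext = ".molden")
  writeLines(c("[Molden Format]", "[Atoms] AU", "H 1 1 0 0 0"), path3)
  expect_error(read_molden(path3), class = "lapnet_parse")

  expect_error(read_molden(file.path(tempdir(), "no_such_file.molden")),
               class = "lapnet_io")
})

test_that("writer validates invariants before writing", {
  w <- single_s_wavefunction()
  w$occupations <- 3          # breaks the [0, 2] occupation invariant
  path <- withr::local_tempfile(fileext = ".molden")
  expect_error(write_molden(w, path), class = "lapnet_validation")
  expect_false(file.exists(path))
  expect_error(write_molden(list(), path), class = "lapnet_validation")
})

test_that("angstrom coordinates are converted to bohr at parse time", {
  au <- withr::local_tempfile(fileext = ".molden")
  angs <- withr::local_tempfile(fileext = ".molden")
  base <- c("[GTO]", "1 0", " s 1 1.00", "  1.0 1.0", "", "[MO]",
            " Occup= 2", "  1 1.0")
  writeLines(c("[Molden Format]", "[Atoms] AU", "H 1 1 1.0 0 0", base), au)
  writeLines(c("[Molden Format]", "[Atoms] (Angs)", "H 1 1 1.0 0 0", base), angs)
  expect_equal(read_molden(au)$atoms$x, 1.0)
  expect_equal(read_molden(angs)$atoms$x, 1.8897259886, tolerance = 1e-9)
})

test_that("spherical [5D] d shells expand to the Cartesian set", {
  # one d shell, MO = pure d0; compare against the Cartesian combination
  # z2 - x2/2 - y2/2 built directly
  path <- withr::local_tempfile(fileext = ".molden")
  writeLines(c("[Molden Format]", "[Atoms] AU", "C 1 6 0 0 0", "[5D]", "[GTO]",
               "1 0", " d 1 1.00", "  0.8 1.0", "", "[MO]",
               " Occup= 2", "  1 1.0", "  2 0.0", "  3 0.0", "  4 0.0",
               "  5 0.0"), path)
  w5 <- read_molden(path)
  expect_equal(ncol(w5$mo_coefficients), 6L)
  wc <- wavefunction(data.frame(element = "C", index = 1L, x = 0, y = 0, z = 0),
                     list(basis_shell(1L, "d", 0.8, 1)),
                     matrix(c(-0.5, -0.5, 1, 0, 0, 0), 1, 6), 2)
  set.seed(4)
  pts <- matrix(rnorm(60), 20, 3)
  expect_equal(evaluate_density(w5, pts), evaluate_density(wc, pts),
               tolerance = 1e-10)
})

test_that("electron_count equals the sum of occupations", {
  expect_equal(electron_count(single_s_wavefunction(occ = 2)), 2)
  w <- wavefunction(data.frame(element = "H", index = 1L, x = 0, y = 0, z = 0),
                    list(basis_shell(1L, "s", 1, 1)),
                    matrix(1, 5, 1), rep(2, 5))
  expect_equal(electron_count(w), 10)
  expect_equal(electron_count(formaldehyde_promolecule()), 16)
})

test_that("basis functions are renormalized to unit self-overlap on load", {
  # a deliberately unnormalized contraction integrates to occ electrons
  w <- wavefunction(data.frame(element = "H", index = 1L, x = 0, y = 0, z = 0),
                    list(basis_shell(1L, "s", c(0.5, 2.0), c(3.7, 1.1))),
                    matrix(1, 1, 1), 2)
  g <- seq(-7, 7, by = 0.15)
  pts <- as.matrix(expand.grid(x = g, y = g, z = 0))
  # radial integral via 2D slice is not enough; use the full 3D grid coarser
  g3 <- seq(-6.5, 6.5, by = 0.25)
  pts3 <- as.matrix(expand.grid(x = g3, y = g3, z = g3))
  rho <- evaluate_density(w, pts3)
  expect_equal(sum(rho) * 0.25^3, 2, tolerance = 1e-3)
})
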