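## Analytic evaluation of the electron density rho(r) and its Laplacian
## from a Gaussian-basis wavefunction, plus the 2D evaluation plane through
## the carbonyl group and the nucleophile.
##
## All derivatives are analytic: for f(x) = x^a exp(-alpha x^2),
##   f'  = (a x^(a-1) - 2 alpha x^(a+1)) exp(-alpha x^2)
##   f'' = (a(a-1) x^(a-2) - 2 alpha (2a+1) x^a + 4 alpha^2 x^(a+2)) exp(.)
## and rho = sum_i occ_i phi_i^2 gives
##   lap(rho) = sum_i occ_i (2 phi_i lap(phi_i) + 2 |grad phi_i|^2).

as_points_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop_lapnet("points must be a 3-column matrix or a 3-vector",
                  class = "lapnet_validation")
    points <- matrix(points, 1L, 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop_lapnet("points must have 3 columns", class = "lapnet_validation")
  storage.mode(points) <- "double"
  points
}

# x^k with the convention that negative k (arising from a*x^(a-1) at a=0)
# never gets evaluated because its coefficient is zero.
pow_or_zero <- function(x, k) {
  if (k < 0) return(0) else if (k == 0) return(1) else x^k
}

# Evaluate all expanded Cartesian basis functions (and optionally their
# gradients and Laplacians) at a set of points. Returns n x K matrices.
evaluate_basis <- function(wfn, points, derivs = FALSE) {
  pts <- as_points_matrix(points)
  bf <- expand_basis(wfn)
  n <- nrow(pts); K <- length(bf)
  chi <- matrix(0, n, K)
  if (derivs) {
    dx <- matrix(0, n, K); dy <- matrix(0, n, K); dz <- matrix(0, n, K)
    lap <- matrix(0, n, K)
  }
  for (k in seq_len(K)) {
    f <- bf[[k]]
    X <- pts[, 1] - f$center[1]
    Y <- pts[, 2] - f$center[2]
    Z <- pts[, 3] - f$center[3]
    R2 <- X * X + Y * Y + Z * Z
    a <- f$a; b <- f$b; cc <- f$c
    L <- a + b + cc
    if (L == 0L) {
      # s function fast path
      for (p in seq_along(f$alpha)) {
        al <- f$alpha[p]
        e <- f$coef[p] * exp(-al * R2)
        chi[, k] <- chi[, k] + e
        if (derivs) {
          dx[, k] <- dx[, k] - 2 * al * X * e
          dy[, k] <- dy[, k] - 2 * al * Y * e
          dz[, k] <- dz[, k] - 2 * al * Z * e
          lap[, k] <- lap[, k] + e * (4 * al * al * R2 - 6 * al)
        }
      }
      next
    }
    if (L == 1L) {
      # p function fast path; axis with the unit power
      A1 <- if (a == 1L) X else if (b == 1L) Y else Z
      for (p in seq_along(f$alpha)) {
        al <- f$alpha[p]
        e <- f$coef[p] * exp(-al * R2)
        chi[, k] <- chi[, k] + e * A1
        if (derivs) {
          gx <- -2 * al * A1 * X; gy <- -2 * al * A1 * Y; gz <- -2 * al * A1 * Z
          if (a == 1L) gx <- gx + 1 else if (b == 1L) gy <- gy + 1 else gz <- gz + 1
          dx[, k] <- dx[, k] + e * gx
          dy[, k] <- dy[, k] + e * gy
          dz[, k] <- dz[, k] + e * gz
          lap[, k] <- lap[, k] + e * A1 * (4 * al * al * R2 - 10 * al)
        }
      }
      next
    }
    PA <- pow_or_zero(X, a); PB <- pow_or_zero(Y, b); PC <- pow_or_zero(Z, cc)
    for (p in seq_along(f$alpha)) {
      al <- f$alpha[p]
      e <- f$coef[p] * exp(-al * R2)
      chi[, k] <- chi[, k] + e * PA * PB * PC
      if (derivs) {
        fa1 <- a * pow_or_zero(X, a - 1) - 2 * al * pow_or_zero(X, a + 1)
        fb1 <- b * pow_or_zero(Y, b - 1) - 2 * al * pow_or_zero(Y, b + 1)
        fc1 <- cc * pow_or_zero(Z, cc - 1) - 2 * al * pow_or_zero(Z, cc + 1)
        fa2 <- a * (a - 1) * pow_or_zero(X, a - 2) -
          2 * al * (2 * a + 1) * PA + 4 * al * al * pow_or_zero(X, a + 2)
        fb2 <- b * (b - 1) * pow_or_zero(Y, b - 2) -
          2 * al * (2 * b + 1) * PB + 4 * al * al * pow_or_zero(Y, b + 2)
        fc2 <- cc * (cc - 1) * pow_or_zero(Z, cc - 2) -
          2 * al * (2 * cc + 1) * PC + 4 * al * al * pow_or_zero(Z, cc + 2)
        dx[, k] <- dx[, k] + e * fa1 * PB * PC
        dy[, k] <- dy[, k] + e * PA * fb1 * PC
        dz[, k] <- dz[, k] + e * PA * PB * fc1
        lap[, k] <- lap[, k] + e * (fa2 * PB * PC + PA * fb2 * PC + PA * PB * fc2)
      }
    }
  }
  if (derivs) list(chi = chi, dx = dx, dy = dy, dz = dz, lap = lap)
  else list(chi = chi)
}

#' Evaluate the electron density at arbitrary points
#'
#' \eqn{\rho(r) = \sum_i occ_i |\phi_i(r)|^2} with the molecular orbitals
#' expanded in Cartesian Gaussians. Non-negative by construction.
#'
#' @param wfn a [wavefunction()].
#' @param points numeric matrix with one 3D point (bohr) per row, or a
#'   single 3-vector.
#' @return density values in bohr^-3, one per point.
#' @export
evaluate_density <- function(wfn, points) {
  pts <- as_points_matrix(points)
  out <- numeric(nrow(pts))
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / 50000))
  Ct <- t(wfn$mo_coefficients)
  for (ii in idx) {
    B <- evaluate_basis(wfn, pts[ii, , drop = FALSE])
    Phi <- B$chi %*% Ct
    out[ii] <- drop((Phi * Phi) %*% wfn$occupations)
  }
  pmax(out, 0)
}

#' Evaluate the Laplacian of the electron density at arbitrary points
#'
#' Analytic second derivatives of the Gaussian expansion, summed over the
#' three Cartesian components. Negative values mark charge concentration,
#' positive values charge depletion.
#'
#' @inheritParams evaluate_density
#' @return Laplacian values in bohr^-5, one per point.
#' @export
evaluate_laplacian <- function(wfn, points) {
  pts <- as_points_matrix(points)
  out <- numeric(nrow(pts))
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / 50000))
  Ct <- t(wfn$mo_coefficients)
  occ <- wfn$occupations
  for (ii in idx) {
    B <- evaluate_basis(wfn, pts[ii, , drop = FALSE], derivs = TRUE)
    Phi <- B$chi %*% Ct
    Lap <- B$lap %*% Ct
    Gx <- B$dx %*% Ct; Gy <- B$dy %*% Ct; Gz <- B$dz %*% Ct
    out[ii] <- 2 * drop((Phi * Lap) %*% occ) +
      2 * drop((Gx * Gx + Gy * Gy + Gz * Gz) %*% occ)
  }
  out
}

#' Construct the evaluation plane through carbonyl C, O and the nucleophile
#'
#' The plane frame is canonical: origin at the carbonyl carbon, `axis_u`
#' pointing from C toward O, `axis_v` perpendicular in-plane with the
#' nucleophile at non-negative v. Extents cover all three atoms plus
#' `padding` on every side (the grid is symmetric about the origin).
#'
#' @param wfn a [wavefunction()].
#' @param c_idx,o_idx,nu_idx atom indices (values of `wfn$atoms$index`) of
#'   the carbonyl carbon, carbonyl oxygen and nucleophile atom.
#' @param padding margin beyond the atoms, bohr.
#' @param resolution grid points per bohr.
#' @return an object of class `grid_plane` with fields `origin`, `axis_u`,
#'   `axis_v`, `extent_u`, `extent_v` (half-widths, bohr), `n_u`, `n_v`, and
#'   `atom_marks` (in-plane coordinates of C, O, Nu).
#' @export
plane_from_atoms <- function(wfn, c_idx, o_idx, nu_idx, padding = 4,
                             resolution = 20) {
  stopifnot(inherits(wfn, "wavefunction"))
  idx <- c(c_idx, o_idx, nu_idx)
  row <- match(idx, wfn$atoms$index)
  if (any(is.na(row)))
    stop_lapnet("atom index not present in wavefunction: ",
                paste(idx[is.na(row)], collapse = ", "),
                class = "lapnet_geometry")
  if (anyDuplicated(idx))
    stop_lapnet("carbonyl C, O and nucleophile must be distinct atoms",
                class = "lapnet_geometry")
  P <- unname(as.matrix(wfn$atoms[row, c("x", "y", "z")]))
  C <- P[1, ]; O <- P[2, ]; Nu <- P[3, ]
  co <- O - C
  d_co <- sqrt(sum(co^2))
  if (d_co < 1e-8)
    stop_lapnet("carbonyl C and O coincide", class = "lapnet_geometry")
  e_u <- co / d_co
  w <- Nu - C
  v_comp <- w - sum(w * e_u) * e_u
  d_v <- sqrt(sum(v_comp^2))
  if (d_v < 1e-8)
    stop_lapnet("C, O and nucleophile are collinear: no unique plane",
                class = "lapnet_geometry")
  e_v <- v_comp / d_v
  marks <- data.frame(atom = c("C", "O", "Nu"),
                      u = c(0, d_co, sum(w * e_u)),
                      v = c(0, 0, d_v))
  extent_u <- max(abs(c(min(marks$u) - padding, max(marks$u) + padding)))
  extent_v <- max(abs(c(min(marks$v) - padding, max(marks$v) + padding)))
  n_u <- max(2L, as.integer(round(2 * extent_u * resolution)) + 1L)
  n_v <- max(2L, as.integer(round(2 * extent_v * resolution)) + 1L)
  structure(list(origin = C, axis_u = e_u, axis_v = e_v,
                 extent_u = extent_u, extent_v = extent_v,
                 n_u = n_u, n_v = n_v, atom_marks = marks),
            class = "grid_plane")
}

#' Grid coordinates of a plane
#' @param plane a `grid_plane`.
#' @return list with vectors `u` (length `n_u`) and `v` (length `n_v`), bohr.
#' @export
grid_coords <- function(plane) {
  stopifnot(inherits(plane, "grid_plane"))
  list(u = seq(-plane$extent_u, plane$extent_u, length.out = plane$n_u),
       v = seq(-plane$extent_v, plane$extent_v, length.out = plane$n_v))
}

# All grid points as 3D coordinates, u index varying fastest.
plane_points3d <- function(plane) {
  g <- grid_coords(plane)
  U <- rep(g$u, times = plane$n_v)
  V <- rep(g$v, each = plane$n_u)
  cbind(plane$origin[1] + U * plane$axis_u[1] + V * plane$axis_v[1],
        plane$origin[2] + U * plane$axis_u[2] + V * plane$axis_v[2],
        plane$origin[3] + U * plane$axis_u[3] + V * plane$axis_v[3])
}

#' Sample a scalar field on a plane grid
#'
#' Evaluates either the electron density or its Laplacian at every grid
#' point of `plane`.
#'
#' @param wfn a [wavefunction()].
#' @param plane a `grid_plane` from [plane_from_atoms()].
#' @param field_kind `"laplacian"` (default) or `"density"`.
#' @return an object of class `scalar_field_map` with fields `plane`,
#'   `values` (`n_u` x `n_v` matrix), `field_kind` and `atom_marks`.
#' @export
sample_map <- function(wfn, plane, field_kind = c("laplacian", "density")) {
  field_kind <- match.arg(field_kind)
  stopifnot(inherits(plane, "grid_plane"))
  pts <- plane_points3d(plane)
  vals <- if (field_kind == "density") evaluate_density(wfn, pts)
  else evaluate_laplacian(wfn, pts)
  if (any(!is.finite(vals)))
    stop_lapnet("non-finite field values on the plane grid",
                class = "lapnet_numeric")
  structure(list(plane = plane,
                 values = matrix(vals, plane$n_u, plane$n_v),
                 field_kind = field_kind,
                 atom_marks = plane$atom_marks),
            class = "scalar_field_map")
}

#' @export
print.scalar_field_map <- function(x, ...) {
  cat("scalar_field_map:", x$field_kind, "on", x$plane$n_u, "x", x$plane$n_v,
      "grid\n")
  cat("  extent u:", signif(2 * x$plane$extent_u, 4), "bohr, v:",
      signif(2 * x$plane$extent_v, 4), "bohr\n")
  cat("  value range:", paste(signif(range(x$values), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Save or load a field map as a self-describing container
#'
#' Runtime persistence of sampled maps (grid metadata plus the value
#' array) in R's native serialization; use [export_map_text()] for a
#' plain-text view.
#'
#' @param map a `scalar_field_map`.
#' @param path file path.
#' @return `save_map` returns `path` invisibly; `load_map` returns the map.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_field_map"))
  saveRDS(map, path)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  map <- readRDS(path)
  if (!inherits(map, "scalar_field_map"))
    stop_lapnet("not a saved scalar_field_map: ", path, class = "lapnet_io")
  map
}

#' Export a field map as plain text
#'
#' Writes a small header (grid metadata and atom marks) followed by the
#' value matrix, for debugging and external plotting.
#'
#' @param map a `scalar_field_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_map_text <- function(map, path) {
  stopifnot(inherits(map, "scalar_field_map"))
  hdr <- c(paste("# field_kind", map$field_kind),
           paste("# n_u", map$plane$n_u, "n_v", map$plane$n_v),
           paste("# extent_u", map$plane$extent_u, "extent_v", map$plane$extent_v),
           paste("# atom", map$atom_marks$atom, "u", map$atom_marks$u,
                 "v", map$atom_marks$v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
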