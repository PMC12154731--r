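## Internal helpers shared across modules.

# 1 angstrom in bohr (CODATA)
BOHR_PER_ANGSTROM <- 1.8897259886

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lapnet <- function(..., class) {
  stop(structure(class = c(class, "lapnet_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
double_factorial <- function(n) {
  # (2k-1)!! for the small k needed by s/p/d Cartesian Gaussians; (-1)!! = 1
  vapply(n, function(m) if (m <= 0) 1 else prod(seq(m, 1, by = -2)), numeric(1))
}

#' Bilinear interpolation on a regular grid
#'
#' @param u_grid,v_grid strictly increasing grid coordinates.
#' @param values matrix of dim `c(length(u_grid), length(v_grid))`.
#' @param u,v query coordinates (equal length). Points outside the grid
#'   return `NA`.
#' @return numeric vector of interpolated values.
#' @noRd
bilinear_interp <- function(u_grid, v_grid, values, u, v) {
  nu <- length(u_grid); nv <- length(v_grid)
  du <- (u_grid[nu] - u_grid[1]) / (nu - 1)
  dv <- (v_grid[nv] - v_grid[1]) / (nv - 1)
  fi <- (u - u_grid[1]) / du
  fj <- (v - v_grid[1]) / dv
  i0 <- pmin(pmax(floor(fi), 0), nu - 2)
  j0 <- pmin(pmax(floor(fj), 0), nv - 2)
  ti <- fi - i0
  tj <- fj - j0
  out_of_range <- fi < -1e-9 | fi > nu - 1 + 1e-9 | fj < -1e-9 | fj > nv - 1 + 1e-9
  i0 <- i0 + 1L; j0 <- j0 + 1L           # 1-based corner
  idx <- function(i, j) values[cbind(i, j)]
  val <- (1 - ti) * (1 - tj) * idx(i0, j0) +
    ti * (1 - tj) * idx(i0 + 1L, j0) +
    (1 - ti) * tj * idx(i0, j0 + 1L) +
    ti * tj * idx(i0 + 1L, j0 + 1L)
  val[out_of_range] <- NA_real_
  val
}

# Deterministic sub-seed derivation: keeps derived seeds positive 32-bit.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1299721) %% 2147483587) + 1L
}
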