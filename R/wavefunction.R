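## Gaussian-basis wavefunction container.
##
## A `wavefunction` holds everything the density evaluator needs: atom
## positions (bohr), contracted Gaussian shells (s/p/d), and the molecular
## orbitals of a closed-shell single determinant as a coefficient matrix over
## the Cartesian-expanded basis together with per-MO occupations.

#' Construct a basis shell
#'
#' A contracted Gaussian shell attached to one atom. Only s, p and d angular
#' momenta are supported. Contraction coefficients refer to normalized
#' primitives; shells are renormalized on construction so every expanded
#' Cartesian basis function has unit self-overlap.
#'
#' @param atom 1-based index of the atom carrying the shell.
#' @param l angular momentum, one of `"s"`, `"p"`, `"d"`.
#' @param exponents positive primitive exponents (bohr^-2).
#' @param coefficients contraction coefficients, one per primitive.
#' @param cartesian_d for d shells, whether the original representation was
#'   the 6-component Cartesian set (`TRUE`, internal standard) or the
#'   5-component spherical set. Internally everything is Cartesian; the flag
#'   records provenance.
#' @return an object of class `basis_shell`.
#' @export
basis_shell <- function(atom, l, exponents, coefficients, cartesian_d = TRUE) {
  l <- match.arg(l, c("s", "p", "d"))
  if (length(exponents) < 1L)
    stop_lapnet("basis shell needs at least one primitive", class = "lapnet_validation")
  if (any(!is.finite(exponents)) || any(exponents <= 0))
    stop_lapnet("basis shell exponents must be positive and finite",
                class = "lapnet_validation")
  if (length(coefficients) != length(exponents))
    stop_lapnet("one contraction coefficient per primitive required",
                class = "lapnet_validation")
  structure(list(atom = as.integer(atom), l = l,
                 exponents = as.numeric(exponents),
                 coefficients = as.numeric(coefficients),
                 cartesian_d = isTRUE(cartesian_d)),
            class = "basis_shell")
}

# Cartesian monomial powers per shell type, Molden component order.
cartesian_components <- function(l) {
  switch(l,
         s = matrix(c(0, 0, 0), ncol = 3),
         p = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
         d = rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                   c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
         stop_lapnet("unsupported angular momentum '", l, "'",
                     class = "lapnet_unsupported"))
}

n_cartesian <- function(l) nrow(cartesian_components(l))

# Normalization constant of a primitive Cartesian Gaussian x^a y^b z^c e^(-alpha r^2)
primitive_norm <- function(alpha, a, b, c) {
  L <- a + b + c
  (2 * alpha / pi)^0.75 * (4 * alpha)^(L / 2) /
    sqrt(double_factorial(2 * a - 1) * double_factorial(2 * b - 1) *
           double_factorial(2 * c - 1))
}

# Self-overlap of a contracted shell (component-independent; uses the axial
# component x^l). Coefficients are taken relative to normalized primitives.
shell_self_overlap <- function(shell) {
  l_num <- match(shell$l, c("s", "p", "d")) - 1L
  a <- l_num; b <- 0L; c <- 0L
  alpha <- shell$exponents
  coef <- shell$coefficients
  N <- primitive_norm(alpha, a, b, c)
  gam <- outer(alpha, alpha, "+")
  olap <- double_factorial(2 * a - 1) * double_factorial(2 * b - 1) *
    double_factorial(2 * c - 1) / (2 * gam)^(a + b + c) * (pi / gam)^1.5
  drop(t(coef * N) %*% (olap %*% (coef * N)))
}

# Rescale contraction coefficients so each Cartesian component has unit norm.
normalize_shell <- function(shell) {
  s <- shell_self_overlap(shell)
  if (!is.finite(s) || s <= 0)
    stop_lapnet("degenerate basis shell (non-positive self-overlap)",
                class = "lapnet_validation")
  shell$coefficients <- shell$coefficients / sqrt(s)
  shell
}

#' Construct a closed-shell Gaussian-basis wavefunction
#'
#' @param atoms data.frame with columns `element` (symbol), `index`
#'   (1-based, unique), `x`, `y`, `z` (bohr).
#' @param shells list of [basis_shell()] objects.
#' @param mo_coefficients numeric matrix, one row per molecular orbital, one
#'   column per expanded Cartesian basis function.
#' @param occupations per-MO electron counts in `[0, 2]`.
#' @param renormalize renormalize shells to unit basis-function self-overlap
#'   (default `TRUE`; already-normalized shells are unchanged).
#' @return an object of class `wavefunction`.
#' @export
wavefunction <- function(atoms, shells, mo_coefficients, occupations,
                         renormalize = TRUE) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L)
    stop_lapnet("atoms must be a nonempty data.frame", class = "lapnet_validation")
  need <- c("element", "index", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop_lapnet("atoms must have columns ", paste(need, collapse = ", "),
                class = "lapnet_validation")
  if (anyDuplicated(atoms$index))
    stop_lapnet("atom indices must be unique", class = "lapnet_validation")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_lapnet("atom positions must be finite", class = "lapnet_validation")
  shells <- lapply(shells, function(s) {
    if (!inherits(s, "basis_shell"))
      stop_lapnet("shells must be basis_shell objects", class = "lapnet_validation")
    if (!s$atom %in% atoms$index)
      stop_lapnet("shell attached to unknown atom index ", s$atom,
                  class = "lapnet_validation")
    if (renormalize) normalize_shell(s) else s
  })
  mo_coefficients <- as.matrix(mo_coefficients)
  nb <- sum(vapply(shells, function(s) n_cartesian(s$l), integer(1)))
  if (ncol(mo_coefficients) != nb)
    stop_lapnet("MO coefficient columns (", ncol(mo_coefficients),
                ") disagree with expanded basis dimension (", nb, ")",
                class = "lapnet_validation")
  occupations <- as.numeric(occupations)
  if (length(occupations) != nrow(mo_coefficients))
    stop_lapnet("one occupation per MO required", class = "lapnet_validation")
  if (any(occupations < -1e-12) || any(occupations > 2 + 1e-12))
    stop_lapnet("occupations must lie in [0, 2]", class = "lapnet_validation")
  # canonical shell order: grouped by atom (as the Molden [GTO] section is
  # written); MO columns are permuted alongside their shells
  shell_atom_row <- match(vapply(shells, `[[`, integer(1), "atom"),
                          atoms$index)
  ord <- order(shell_atom_row)
  if (!identical(ord, seq_along(shells))) {
    widths <- vapply(shells, function(s) n_cartesian(s$l), integer(1))
    starts <- cumsum(c(0L, widths[-length(widths)]))
    col_perm <- unlist(lapply(ord, function(k) starts[k] + seq_len(widths[k])))
    shells <- shells[ord]
    mo_coefficients <- mo_coefficients[, col_perm, drop = FALSE]
  }
  structure(list(atoms = atoms, shells = shells,
                 mo_coefficients = mo_coefficients,
                 occupations = occupations),
            class = "wavefunction")
}

#' @export
print.wavefunction <- function(x, ...) {
  cat("Gaussian-basis wavefunction\n")
  cat("  atoms:", nrow(x$atoms), paste0("(", paste(x$atoms$element, collapse = " "), ")"), "\n")
  cat("  shells:", length(x$shells), " expanded basis functions:",
      ncol(x$mo_coefficients), "\n")
  cat("  MOs:", nrow(x$mo_coefficients), " electrons:", electron_count(x), "\n")
  invisible(x)
}

#' Total electron count of a wavefunction
#'
#' The sum of molecular-orbital occupations; equals the integral of the
#' electron density over all space.
#'
#' @param wfn a [wavefunction()].
#' @return electron count (numeric scalar).
#' @export
electron_count <- function(wfn) {
  stopifnot(inherits(wfn, "wavefunction"))
  sum(wfn$occupations)
}

# Flatten the shell list to one entry per Cartesian basis function:
# center (3-vector, bohr), powers a,b,c, primitive exponents, coefficients
# including the primitive normalization constants.
expand_basis <- function(wfn) {
  out <- vector("list", ncol(wfn$mo_coefficients))
  k <- 0L
  pos <- as.matrix(wfn$atoms[, c("x", "y", "z")])
  rownames(pos) <- NULL
  row_of <- match(vapply(wfn$shells, `[[`, integer(1), "atom"), wfn$atoms$index)
  for (si in seq_along(wfn$shells)) {
    sh <- wfn$shells[[si]]
    comps <- cartesian_components(sh$l)
    for (ci in seq_len(nrow(comps))) {
      k <- k + 1L
      a <- comps[ci, 1]; b <- comps[ci, 2]; cc <- comps[ci, 3]
      out[[k]] <- list(center = pos[row_of[si], ],
                       a = a, b = b, c = cc,
                       alpha = sh$exponents,
                       coef = sh$coefficients *
                         primitive_norm(sh$exponents, a, b, cc))
    }
  }
  out
}

# Transformation from the 5 normalized spherical d functions (Molden order
# d0, d+1, d-1, d+2, d-2) to the 6 normalized Cartesian d functions (Molden
# order xx, yy, zz, xy, xz, yz).
spherical_d_to_cartesian <- function() {
  rbind(
    c(-0.5, -0.5, 1, 0, 0, 0),                    # d0 = z2 - (x2+y2)/2
    c(0, 0, 0, 0, 1, 0),                          # d+1 = xz
    c(0, 0, 0, 0, 0, 1),                          # d-1 = yz
    c(sqrt(3) / 2, -sqrt(3) / 2, 0, 0, 0, 0),     # d+2 = sqrt(3)/2 (x2 - y2)
    c(0, 0, 0, 1, 0, 0))                          # d-2 = xy
}
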