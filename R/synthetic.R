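## Synthetic labeled inputs for every pipeline stage.
##
## Two tiers share the LabeledImage contract:
##  * physical  - promolecular Gaussian wavefunctions over a carbonyl
##    geometry, with a tunable attack-side charge-rearrangement lobe on the
##    carbon valence shell, pushed through the full wavefunction -> map ->
##    contour -> render -> crop pipeline;
##  * graphical - parametric valence-shell contour images (closed envelope
##    vs. envelope with an attack-side gap) drawn directly in image space,
##    for cheap classifier tests.
##
## The promolecular shell parameters are fixed in-code constants chosen for
## topological realism of the zero contour (core depletion, valence-shell
## concentration ring, outer depletion), not for physical accuracy.

# element -> s-shell exponents (bohr^-2) and electrons per shell
PROMOLECULE_SHELLS <- list(
  H = data.frame(alpha = 0.30, electrons = 1),
  C = data.frame(alpha = c(10.0, 0.45), electrons = c(2, 4)),
  N = data.frame(alpha = c(14.0, 0.55), electrons = c(2, 5)),
  O = data.frame(alpha = c(18.0, 0.65), electrons = c(2, 6)),
  S = data.frame(alpha = c(40.0, 2.6, 0.40), electrons = c(2, 8, 6))
)

# exponent of the carbon p lobe used for the attack-side rearrangement;
# the admissible mixing range is capped where the depletion response stops
# growing monotonically (beyond ~0.3 the p^2 density term refills the
# attack side)
LOBE_P_EXPONENT <- 0.45
LOBE_STRENGTH_MAX <- 0.3

#' Build a carbonyl + nucleophile model geometry
#'
#' A formaldehyde-like carbonyl fragment (C, O, two substituent H slightly
#' out of plane) plus a nucleophile atom approaching in the C/O/Nu plane.
#'
#' @param attack_distance C-to-nucleophile distance, angstrom.
#' @param attack_angle O=C..Nu angle, degrees.
#' @param nu_element element symbol of the nucleophile atom.
#' @return a list with `atoms` (data.frame, coordinates in bohr) and the
#'   atom indices `c_idx`, `o_idx`, `nu_idx`.
#' @export
carbonyl_geometry <- function(attack_distance = 2.9, attack_angle = 105,
                              nu_element = "O") {
  A <- BOHR_PER_ANGSTROM
  th <- attack_angle * pi / 180
  atoms <- data.frame(
    element = c("C", "O", "H", "H", nu_element),
    index = 1:5,
    x = c(0, 1.22 * A, -0.55 * A, -0.55 * A,
          attack_distance * A * cos(th)),
    y = c(0, 0, 0.92 * A, -0.92 * A,
          attack_distance * A * sin(th)),
    z = c(0, 0, 0.30 * A, -0.30 * A, 0),
    stringsAsFactors = FALSE)
  list(atoms = atoms, c_idx = 1L, o_idx = 2L, nu_idx = 5L)
}

#' Build a promolecular wavefunction with a tunable attack-side lobe
#'
#' The density is a sum of atom-centered spherical Gaussian shells
#' (element-parameterized in-code constants). When `lobe_strength > 0` the
#' carbon valence orbitals are sp-hybridized away from the nucleophile:
#' `phi = sqrt(1 - lobe) s + sqrt(lobe) p_away`, which depletes density on
#' the attack side while conserving the electron count exactly (s and p on
#' the same center are orthonormal). Because the density is a sum of
#' squared orbitals with non-negative occupations it is non-negative by
#' construction for any admissible `lobe_strength`.
#'
#' @param geometry a geometry list as from [carbonyl_geometry()]: `atoms`
#'   data.frame (bohr) plus `c_idx`, `o_idx`, `nu_idx`.
#' @param lobe_strength dimensionless mixing weight in
#'   `[0, 0.6]`; 0 leaves every atom a closed spherical shell.
#' @return a [wavefunction()].
#' @export
make_promolecule <- function(geometry, lobe_strength = 0) {
  atoms <- geometry$atoms
  if (!is.finite(lobe_strength) || lobe_strength < 0 ||
      lobe_strength > LOBE_STRENGTH_MAX)
    stop_lapnet("lobe_strength must lie in [0, ", LOBE_STRENGTH_MAX,
                "]; got ", lobe_strength, class = "lapnet_generator")
  m <- NULL
  if (lobe_strength > 0) {
    if (is.null(geometry$nu_idx))
      stop_lapnet("a nucleophile index is required when lobe_strength > 0",
                  class = "lapnet_generator")
    C <- unlist(atoms[atoms$index == geometry$c_idx, c("x", "y", "z")])
    Nu <- unlist(atoms[atoms$index == geometry$nu_idx, c("x", "y", "z")])
    m <- C - Nu
    nm <- sqrt(sum(m^2))
    if (nm < 1e-8)
      stop_lapnet("carbon and nucleophile coincide", class = "lapnet_geometry")
    m <- m / nm   # unit vector pointing away from the nucleophile
  }

  shells <- list()
  mo_rows <- list()
  occs <- numeric(0)
  col <- 0L
  for (i in seq_len(nrow(atoms))) {
    el <- atoms$element[i]
    tab <- PROMOLECULE_SHELLS[[el]]
    if (is.null(tab))
      stop_lapnet("no promolecular shell parameters for element '", el, "'",
                  class = "lapnet_generator")
    is_lobe_center <- atoms$index[i] == geometry$c_idx && lobe_strength > 0
    for (s in seq_len(nrow(tab))) {
      shells[[length(shells) + 1L]] <- basis_shell(atoms$index[i], "s",
                                                   tab$alpha[s], 1)
      s_col <- col + 1L
      col <- col + 1L
      valence <- s == nrow(tab)
      p_cols <- NULL
      if (is_lobe_center && valence) {
        shells[[length(shells) + 1L]] <- basis_shell(atoms$index[i], "p",
                                                     LOBE_P_EXPONENT, 1)
        p_cols <- col + 1:3
        col <- col + 3L
      }
      e_left <- tab$electrons[s]
      while (e_left > 1e-12) {
        occ <- min(2, e_left)
        e_left <- e_left - occ
        row <- list(cols = s_col, coefs = 1)
        if (!is.null(p_cols)) {
          row <- list(cols = c(s_col, p_cols),
                      coefs = c(sqrt(1 - lobe_strength),
                                sqrt(lobe_strength) * m))
        }
        mo_rows[[length(mo_rows) + 1L]] <- row
        occs[length(occs) + 1L] <- occ
      }
    }
  }
  n_basis <- col
  Cmat <- matrix(0, length(mo_rows), n_basis)
  for (r in seq_along(mo_rows))
    Cmat[r, mo_rows[[r]]$cols] <- mo_rows[[r]]$coefs
  wavefunction(atoms, shells, Cmat, occs)
}

#' Specification of a synthetic contour-image dataset
#'
#' The generator's defaults define the study conditions: a balanced set of
#' carbonyl frames with thermal-scale geometry jitter and per-class lobe
#' strengths on disjoint ranges, rendered and cropped with the standard
#' conventions.
#'
#' @param n_images number of images.
#' @param class_balance fraction of reactive images in `[0, 1]`.
#' @param geometry_jitter per-coordinate normal displacement, angstrom.
#' @param angle_jitter half-width of the uniform nucleophile-direction
#'   jitter, degrees.
#' @param attack_distance_range uniform sampling range of the
#'   C-to-nucleophile distance, angstrom.
#' @param lobe_range_reactive,lobe_range_nonreactive disjoint lobe-strength
#'   intervals per class.
#' @param tier `"physical"` (full wavefunction pipeline) or `"graphical"`
#'   (parametric contour images).
#' @param map_resolution grid points per bohr for the physical tier.
#' @param padding plane padding, bohr.
#' @param downscale integer block-averaging factor applied to the cropped
#'   image kept in memory for classifier work.
#' @param style a [render_style()].
#' @param seed RNG seed; the dataset is bit-reproducible given the seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images = 100, class_balance = 0.5,
                           geometry_jitter = 0.05, angle_jitter = 10,
                           attack_distance_range = c(2.7, 3.1),
                           lobe_range_reactive = c(0.12, 0.25),
                           lobe_range_nonreactive = c(0, 0.04),
                           tier = c("physical", "graphical"),
                           map_resolution = 10, padding = 4,
                           downscale = 10, style = render_style(),
                           seed = 1) {
  tier <- match.arg(tier)
  if (class_balance < 0 || class_balance > 1)
    stop_lapnet("class_balance must lie in [0, 1]", class = "lapnet_validation")
  lo <- sort(lobe_range_nonreactive); hi <- sort(lobe_range_reactive)
  if (lo[2] >= hi[1])
    stop_lapnet("reactive and nonreactive lobe-strength ranges must be disjoint",
                class = "lapnet_validation")
  structure(list(n_images = as.integer(n_images), class_balance = class_balance,
                 geometry_jitter = geometry_jitter, angle_jitter = angle_jitter,
                 attack_distance_range = attack_distance_range,
                 lobe_range_reactive = hi, lobe_range_nonreactive = lo,
                 tier = tier, map_resolution = map_resolution,
                 padding = padding, downscale = as.integer(downscale),
                 style = style, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# one jittered draw of geometry + lobe strength for a target class
draw_item_params <- function(spec, reactive) {
  rng <- if (reactive) spec$lobe_range_reactive else spec$lobe_range_nonreactive
  lobe <- stats::runif(1, rng[1], rng[2])
  d <- stats::runif(1, spec$attack_distance_range[1],
                    spec$attack_distance_range[2])
  ang <- 105 + stats::runif(1, -spec$angle_jitter, spec$angle_jitter)
  geom <- carbonyl_geometry(attack_distance = d, attack_angle = ang)
  jit <- matrix(stats::rnorm(nrow(geom$atoms) * 3, 0,
                             spec$geometry_jitter * BOHR_PER_ANGSTROM),
                ncol = 3)
  geom$atoms$x <- geom$atoms$x + jit[, 1]
  geom$atoms$y <- geom$atoms$y + jit[, 2]
  geom$atoms$z <- geom$atoms$z + jit[, 3]
  list(geometry = geom, lobe = lobe, attack_distance = d, attack_angle = ang)
}

# physical tier: full pipeline for one frame; returns cropped render + map
synth_physical_frame <- function(params, spec) {
  wfn <- make_promolecule(params$geometry, params$lobe)
  plane <- plane_from_atoms(wfn, params$geometry$c_idx, params$geometry$o_idx,
                            params$geometry$nu_idx, padding = spec$padding,
                            resolution = spec$map_resolution)
  map <- sample_map(wfn, plane, "laplacian")
  full <- render_map(zero_contour(map), map, spec$style)
  list(image = crop_carbonyl(full, map), map = map)
}

# graphical tier: parametric valence-shell contour image (no wavefunction)
synth_graphical_frame <- function(params, spec, reactive) {
  style <- spec$style
  pix <- matrix(style$pos_shade, RENDER_H, RENDER_W)
  pxC <- plane_to_pixel(0, 0)
  pxO <- plane_to_pixel(2.30 + stats::rnorm(1, 0, 0.05), stats::rnorm(1, 0, 0.05))
  rC <- (1.35 + stats::runif(1, -0.1, 0.1)) * PX_PER_BOHR
  rO <- (1.10 + stats::runif(1, -0.1, 0.1)) * PX_PER_BOHR
  band <- 0.35 * PX_PER_BOHR
  rows <- matrix(seq_len(RENDER_H), RENDER_H, RENDER_W)
  cols <- matrix(seq_len(RENDER_W), RENDER_H, RENDER_W, byrow = TRUE)
  dC <- sqrt((rows - pxC$row)^2 + (cols - pxC$col)^2)
  dO <- sqrt((rows - pxO$row)^2 + (cols - pxO$col)^2)
  d <- pmin(dC - rC, dO - rO)
  shell <- d > -band & d < 0
  if (reactive) {
    # carve an attack-side gap: wedge around the C->Nu direction (+v, right)
    ang <- atan2(cols - pxC$col, rows - pxC$row) - pi / 2
    ang <- atan2(sin(ang), cos(ang))
    half <- (14 + stats::runif(1, 0, 14)) * pi / 180
    tilt <- stats::runif(1, -0.25, 0.25)
    shell[abs(ang - tilt) < half & dC < rC + band] <- FALSE
  }
  pix[shell] <- style$neg_shade
  if (style$line) {
    # contour line = morphological boundary of the concentration band
    shift <- function(m, dr, dc) {
      out <- matrix(FALSE, nrow(m), ncol(m))
      r <- seq_len(nrow(m)); c <- seq_len(ncol(m))
      out[pmin(pmax(r + dr, 1), nrow(m)), pmin(pmax(c + dc, 1), ncol(m))] <- m
      out
    }
    interior <- shell & shift(shell, 1, 0) & shift(shell, -1, 0) &
      shift(shell, 0, 1) & shift(shell, 0, -1)
    pix[shell & !interior] <- style$line_shade
  }
  nu_px <- plane_to_pixel(-1.4, 5.3)
  if (style$atom_marks) {
    pix <- rasterize_disc(pix, pxC$row, pxC$col, style$mark_radius, style$mark_shade)
    pix <- rasterize_disc(pix, pxO$row, pxO$col, style$mark_radius, style$mark_shade)
    pix <- rasterize_disc(pix, nu_px$row, nu_px$col, style$mark_radius, style$mark_shade)
  }
  full <- structure(list(pixels = pix, width = RENDER_W, height = RENDER_H,
                         provenance = list(frame_id = NA, cropped = FALSE,
                                           px_per_bohr = PX_PER_BOHR,
                                           u0 = CANVAS_U0, v0 = CANVAS_V0)),
                    class = "rendered_map")
  marks <- data.frame(atom = c("C", "O", "Nu"),
                      u = c(0, (pxO$row - 0.5) / PX_PER_BOHR + CANVAS_U0, -1.4),
                      v = c(0, (pxO$col - 0.5) / PX_PER_BOHR + CANVAS_V0, 5.3))
  stub_map <- structure(list(atom_marks = marks), class = "scalar_field_map")
  list(image = crop_carbonyl(full, stub_map), map = NULL)
}

#' Generate a labeled synthetic contour-image dataset
#'
#' Class counts follow `class_balance` with largest-remainder rounding; the
#' physical tier runs the full promolecule -> map -> contour -> render ->
#' crop pipeline and every stored label is checked against the geometric
#' oracle ([classify_map()]) on the underlying map, regenerating the frame
#' with fresh jitter on disagreement (an overall regeneration rate above 5%
#' aborts). With a fixed seed the dataset (and manifest) is bit-reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; when given, cropped PNGs and a
#'   `manifest.csv` (file, label, class, lobe_strength, seed) are written.
#' @return an object of class `contour_dataset`: `images` (list of
#'   downscaled grayscale matrices), `labels` (1 reactive / 0 nonreactive),
#'   `meta` (per-image metadata data.frame), `spec`, `n_regenerated`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_images
  n_reactive <- as.integer(round(n * spec$class_balance))
  classes <- c(rep(1L, n_reactive), rep(0L, n - n_reactive))
  set.seed(derive_seed(spec$seed, 0))
  classes <- classes[sample.int(n)]
  images <- vector("list", n)
  meta <- data.frame(id = seq_len(n), file = sprintf("synthetic_%05d.png", seq_len(n)),
                     class = ifelse(classes == 1L, "reactive", "nonreactive"),
                     label = classes, lobe_strength = NA_real_,
                     attack_distance = NA_real_, regenerated = 0L,
                     seed = spec$seed, stringsAsFactors = FALSE)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_regen <- 0L
  max_attempts <- 20L
  for (i in seq_len(n)) {
    reactive <- classes[i] == 1L
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      set.seed(derive_seed(spec$seed, i + (attempt - 1L) * n))
      params <- draw_item_params(spec, reactive)
      if (spec$tier == "graphical") {
        frame <- synth_graphical_frame(params, spec, reactive)
        verdict <- if (reactive) "reactive" else "nonreactive"
      } else {
        frame <- synth_physical_frame(params, spec)
        verdict <- classify_map(frame$map)$label
      }
      want <- if (reactive) "reactive" else "nonreactive"
      if (verdict == want) {
        images[[i]] <- downscale_image(frame$image, spec$downscale)
        meta$lobe_strength[i] <- params$lobe
        meta$attack_distance[i] <- params$attack_distance
        meta$regenerated[i] <- attempt - 1L
        n_regen <- n_regen + attempt - 1L
        if (!is.null(dir))
          write_rendered_png(frame$image, file.path(dir, meta$file[i]))
        done <- TRUE
        break
      }
    }
    if (!done)
      stop_lapnet("could not generate an oracle-consistent '", want,
                  "' frame after ", max_attempts, " attempts (item ", i, ")",
                  class = "lapnet_generator")
  }
  if (n_regen > 0.05 * n)
    stop_lapnet("oracle/intended-label regeneration rate ",
                sprintf("%.1f%%", 100 * n_regen / n), " exceeds 5%",
                class = "lapnet_generator")
  if (!is.null(dir))
    utils::write.csv(meta[, c("file", "label", "class", "lobe_strength", "seed")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(list(images = images, labels = classes, meta = meta, spec = spec,
                 n_regenerated = n_regen),
            class = "contour_dataset")
}

#' @export
print.contour_dataset <- function(x, ...) {
  cat("contour_dataset:", length(x$images), "images (",
      sum(x$labels == 1L), "reactive /", sum(x$labels == 0L), "nonreactive ),",
      x$spec$tier, "tier\n")
  cat("  image size:", paste(dim(x$images[[1]]), collapse = " x "),
      " regenerated:", x$n_regenerated, "\n")
  invisible(x)
}

#' Generate a reactive/non-reactive label series with run structure
#'
#' A two-state Markov chain with stationary reactive fraction `p_reactive`
#' and mean reactive run length `mean_run` (frames). The non-reactive mean
#' run length follows from stationarity as
#' `mean_run * (1 - p_reactive) / p_reactive`.
#'
#' @param n_frames series length.
#' @param p_reactive stationary reactive fraction, in (0, 1).
#' @param mean_run mean length of reactive runs, frames (>= 1); the pair is
#'   infeasible if the implied exit probabilities leave `[0, 1]`.
#' @param seed RNG seed.
#' @return a `label_series` data.frame with columns `frame`, `label`.
#' @export
generate_label_series <- function(n_frames, p_reactive, mean_run = 5, seed = 1) {
  if (!(p_reactive > 0 && p_reactive < 1))
    stop_lapnet("p_reactive must lie strictly in (0, 1)", class = "lapnet_parameter")
  if (mean_run < 1)
    stop_lapnet("mean_run must be >= 1", class = "lapnet_parameter")
  q10 <- 1 / mean_run                                   # exit reactive
  q01 <- p_reactive / ((1 - p_reactive) * mean_run)     # exit nonreactive
  if (q01 > 1)
    stop_lapnet("infeasible (p_reactive, mean_run): implied non-reactive ",
                "exit probability ", signif(q01, 4), " exceeds 1",
                class = "lapnet_parameter")
  set.seed(seed)
  lab <- integer(n_frames)
  lab[1] <- stats::rbinom(1, 1, p_reactive)
  if (n_frames > 1) {
    u <- stats::runif(n_frames - 1)
    for (t in 2:n_frames)
      lab[t] <- if (lab[t - 1] == 1L) as.integer(u[t - 1] >= q10)
      else as.integer(u[t - 1] < q01)
  }
  label_series(lab)
}

#' Generate nucleophilic-attack distances from a normal mixture
#'
#' I.i.d. draws from a k-component normal mixture; the defaults correspond
#' to three carbonyl-attack populations at 2.71, 2.88 and 3.05 angstrom
#' with weights 0.29, 0.42 and 0.29.
#'
#' @param weights mixture weights summing to 1.
#' @param means,sds component means and standard deviations, angstrom.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return data.frame with columns `frame`, `distance`.
#' @export
generate_distance_series <- function(weights = c(0.29, 0.42, 0.29),
                                     means = c(2.71, 2.88, 3.05),
                                     sds = c(0.06, 0.06, 0.06),
                                     n = 1000, seed = 1) {
  if (length(weights) != length(means) || length(means) != length(sds))
    stop_lapnet("weights, means and sds must have equal length",
                class = "lapnet_parameter")
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop_lapnet("mixture weights must be non-negative and sum to 1",
                class = "lapnet_parameter")
  if (any(sds <= 0))
    stop_lapnet("mixture standard deviations must be positive",
                class = "lapnet_parameter")
  set.seed(seed)
  if (n == 0) return(data.frame(frame = integer(0), distance = numeric(0)))
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  data.frame(frame = seq_len(n),
             distance = stats::rnorm(n, means[comp], sds[comp]))
}
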