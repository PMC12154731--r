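## Rule-based reactive/non-reactive decision from a Laplacian map.
##
## The rule formalizes the visual criterion used when classifying maps by
## eye: a reactive (activated) carbonyl carbon shows a charge-depletion
## pocket (Laplacian > 0) breaking the valence-shell charge-concentration
## envelope (Laplacian < 0) on the nucleophile side; a non-reactive carbon
## keeps an unbroken concentration envelope across the probe window.
## It is deterministic and serves as the independent labeling oracle for
## synthetic data and as a cross-check of the CNN.

#' Probe parameters for the geometric classifier
#'
#' @param r_min,r_max radial probe window from the carbonyl carbon, bohr.
#'   The window starts outside the inner core-depletion region and ends at
#'   the outer edge of the valence shell.
#' @param n_radii number of radial samples.
#' @param fan_deg the probe ray is fanned this many degrees to either side
#'   of the C-to-nucleophile direction; the most reactive verdict over the
#'   fan is taken (depletion pockets can sit slightly off-axis).
#' @param n_rays number of rays across the fan.
#' @return a list of class `probe_params`.
#' @export
probe_params <- function(r_min = 0.5, r_max = 1.3, n_radii = 41,
                         fan_deg = 15, n_rays = 7) {
  stopifnot(r_min > 0, r_max > r_min, n_radii >= 5, n_rays >= 1)
  structure(list(r_min = r_min, r_max = r_max, n_radii = as.integer(n_radii),
                 fan_deg = fan_deg, n_rays = as.integer(n_rays)),
            class = "probe_params")
}

# Sign pattern of one ray, run-length compressed; the envelope is broken if
# a positive (depletion) stretch sits strictly inside the window before the
# field re-enters the outer positive region, or if no concentration stretch
# exists at all. A leading positive run (tail of the inner core-depletion
# annulus) is ignored.
ray_broken <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (length(vals) < 3) return(NA)
  runs <- rle(vals > 0)
  if (runs$values[1]) {
    runs$values <- runs$values[-1]
    runs$lengths <- runs$lengths[-1]
  }
  if (length(runs$values) == 0L) return(TRUE)   # no shell at all: broken
  length(runs$values) >= 3L                     # concentration - depletion - concentration
}

#' Classify a Laplacian map as reactive or non-reactive
#'
#' Samples the Laplacian along rays from the carbonyl-carbon mark toward
#' the nucleophile (fanned by `probe$fan_deg`) at radii in
#' `[probe$r_min, probe$r_max]` and labels the map `reactive` if the
#' valence-shell concentration envelope is broken by a depletion region on
#' the attack side along any ray, `nonreactive` otherwise. Deterministic.
#'
#' @param map a `scalar_field_map` with `field_kind = "laplacian"` and atom
#'   marks for C and Nu.
#' @param probe a [probe_params()].
#' @return an object of class `reactivity_label` with fields `label`
#'   (`"reactive"` or `"nonreactive"`) and `rationale` (per-ray audit trail).
#' @export
classify_map <- function(map, probe = probe_params()) {
  stopifnot(inherits(map, "scalar_field_map"))
  if (map$field_kind != "laplacian")
    stop_lapnet("classify_map expects a Laplacian map", class = "lapnet_contract")
  marks <- map$atom_marks
  if (is.null(marks) || !all(c("C", "Nu") %in% marks$atom))
    stop_lapnet("atom marks for C and Nu are required", class = "lapnet_contract")
  C <- unlist(marks[marks$atom == "C", c("u", "v")])
  Nu <- unlist(marks[marks$atom == "Nu", c("u", "v")])
  dir0 <- Nu - C
  nd <- sqrt(sum(dir0^2))
  if (nd < 1e-8)
    stop_lapnet("C and Nu marks coincide", class = "lapnet_contract")
  dir0 <- dir0 / nd
  base_angle <- atan2(dir0[2], dir0[1])
  angles <- if (probe$n_rays == 1L) 0 else
    seq(-probe$fan_deg, probe$fan_deg, length.out = probe$n_rays) * pi / 180
  radii <- seq(probe$r_min, probe$r_max, length.out = probe$n_radii)
  g <- grid_coords(map$plane)
  rays <- data.frame(angle_deg = angles * 180 / pi, broken = NA,
                     pattern = NA_character_)
  for (i in seq_along(angles)) {
    th <- base_angle + angles[i]
    u <- C[1] + radii * cos(th)
    v <- C[2] + radii * sin(th)
    vals <- bilinear_interp(g$u, g$v, map$values, u, v)
    rays$broken[i] <- ray_broken(vals)
    sgn <- ifelse(vals[!is.na(vals)] > 0, "+", "-")
    rays$pattern[i] <- paste(rle(sgn)$values, collapse = "")
  }
  label <- if (isTRUE(any(rays$broken))) "reactive" else "nonreactive"
  structure(list(label = label,
                 rationale = list(probe = probe, rays = rays,
                                  radii_bohr = range(radii))),
            class = "reactivity_label")
}

#' @export
print.reactivity_label <- function(x, ...) {
  cat("reactivity_label:", x$label, "\n")
  cat("  ray patterns:", paste(x$rationale$rays$pattern, collapse = " "), "\n")
  invisible(x)
}
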