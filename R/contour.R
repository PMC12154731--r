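## Zero-isovalue contour extraction and deterministic rasterization.
##
## The rendered canvas uses a fixed plane-to-pixel mapping so that identical
## in-plane (u,v) geometry always yields identical pixels: 60 px/bohr, with
## the canvas window u in [-6, 6) bohr (vertical, 720 rows) and v in
## [-6, 10) bohr (horizontal, 960 columns). The carbonyl axis is vertical
## and the nucleophile side (v > 0) extends to the right, which is the side
## removed by the carbonyl-only crop.

RENDER_W <- 960L
RENDER_H <- 720L
CROP_W <- 550L
PX_PER_BOHR <- 60
CANVAS_U0 <- -6
CANVAS_V0 <- -6
# fixed column offset of the C-O midpoint from the crop window's left edge
CROP_ANCHOR_PX <- 357

# (u,v) bohr -> fractional pixel (row, col), row 1 at u = CANVAS_U0
plane_to_pixel <- function(u, v) {
  list(row = (u - CANVAS_U0) * PX_PER_BOHR + 0.5,
       col = (v - CANVAS_V0) * PX_PER_BOHR + 0.5)
}

#' Extract the zero-isovalue contour of a Laplacian map
#'
#' Marching-squares-style level-0 contour lines of the sampled field.
#' A uniformly signed map yields an empty contour set (not an error).
#'
#' @param map a `scalar_field_map` with `field_kind = "laplacian"`.
#' @return an object of class `contour_set`: list of 2-column `(u, v)`
#'   polyline matrices plus per-polyline closed flags.
#' @export
zero_contour <- function(map) {
  stopifnot(inherits(map, "scalar_field_map"))
  if (map$field_kind != "laplacian")
    stop_lapnet("zero_contour expects a Laplacian map", class = "lapnet_contract")
  g <- grid_coords(map$plane)
  if (all(map$values > 0) || all(map$values < 0))   # uniformly signed: no contour
    return(structure(list(polylines = list(), closed = logical(0)),
                     class = "contour_set"))
  cl <- grDevices::contourLines(g$u, g$v, map$values, levels = 0)
  polylines <- lapply(cl, function(p) cbind(u = p$x, v = p$y))
  closed <- vapply(polylines, function(p) {
    nrow(p) > 2 && all(abs(p[1, ] - p[nrow(p), ]) < 1e-12)
  }, logical(1))
  structure(list(polylines = polylines, closed = closed), class = "contour_set")
}

#' Rendering options for contour maps
#'
#' @param fill two-tone fill by the sign of the field (light for depletion,
#'   darker for concentration), as opposed to a line-only monochrome style.
#' @param line draw the zero contour as a solid dark line.
#' @param atom_marks draw small fixed-radius discs at the C, O and Nu marks.
#' @param line_width approximate line thickness, pixels.
#' @param mark_radius atom disc radius, pixels.
#' @param neg_shade,pos_shade,line_shade,mark_shade grayscale levels in
#'   `[0, 1]` for concentration fill, depletion fill/background, contour
#'   line and atom discs.
#' @param frame_id optional provenance tag recorded in the render.
#' @return a list of class `render_style`.
#' @export
render_style <- function(fill = TRUE, line = TRUE, atom_marks = TRUE,
                         line_width = 3, mark_radius = 5,
                         neg_shade = 0.45, pos_shade = 0.92,
                         line_shade = 0, mark_shade = 0, frame_id = NA) {
  structure(list(fill = fill, line = line, atom_marks = atom_marks,
                 line_width = line_width, mark_radius = mark_radius,
                 neg_shade = neg_shade, pos_shade = pos_shade,
                 line_shade = line_shade, mark_shade = mark_shade,
                 frame_id = frame_id),
            class = "render_style")
}

rasterize_disc <- function(pix, row, col, radius, shade) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(pix), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(pix), ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(pix)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  if (nrow(sel)) pix[cbind(rr[sel[, 1]], cc[sel[, 2]])] <- shade
  pix
}

rasterize_polyline <- function(pix, rows, cols, width, shade) {
  # sample each segment at sub-pixel spacing, then stamp a small offset
  # neighborhood for thickness
  n <- length(rows)
  if (n < 2) return(pix)
  dr <- diff(rows); dc <- diff(cols)
  m <- pmax(2L, ceiling(sqrt(dr^2 + dc^2) / 0.4))
  t <- (sequence(m) - 1) / rep(m - 1L, m)
  r <- round(rep(rows[-n], m) + t * rep(dr, m))
  c <- round(rep(cols[-n], m) + t * rep(dc, m))
  half <- max(0L, floor(width / 2))
  off <- expand.grid(dr = -half:half, dc = -half:half)
  off <- off[off$dr^2 + off$dc^2 <= half^2 + 0.5, ]
  R <- rep(r, times = nrow(off)) + rep(off$dr, each = length(r))
  C <- rep(c, times = nrow(off)) + rep(off$dc, each = length(c))
  keep <- R >= 1 & R <= nrow(pix) & C >= 1 & C <= ncol(pix)
  pix[cbind(R[keep], C[keep])] <- shade
  pix
}

#' Render a contour map to the fixed 960 x 720 canvas
#'
#' Deterministic rasterization: the zero contour as a solid line, optional
#' two-tone fill by field sign, and optional atom-mark discs, on the fixed
#' plane-to-pixel mapping. Identical inputs give bit-identical images.
#'
#' @param contours a `contour_set` from [zero_contour()].
#' @param map the `scalar_field_map` the contours were extracted from.
#' @param style a [render_style()].
#' @return an object of class `rendered_map`: grayscale pixel matrix
#'   (`height` x `width`, values in `[0, 1]`) plus provenance.
#' @export
render_map <- function(contours, map, style = render_style()) {
  stopifnot(inherits(contours, "contour_set"), inherits(map, "scalar_field_map"))
  pix <- matrix(style$pos_shade, RENDER_H, RENDER_W)
  g <- grid_coords(map$plane)
  if (style$fill) {
    # the canvas axes are aligned with the (u,v) grid, so the bilinear
    # interpolation separates into per-row and per-column index vectors
    u_cent <- (seq_len(RENDER_H) - 0.5) / PX_PER_BOHR + CANVAS_U0
    v_cent <- (seq_len(RENDER_W) - 0.5) / PX_PER_BOHR + CANVAS_V0
    nu <- length(g$u); nv <- length(g$v)
    du <- (g$u[nu] - g$u[1]) / (nu - 1)
    dv <- (g$v[nv] - g$v[1]) / (nv - 1)
    fi <- (u_cent - g$u[1]) / du
    fj <- (v_cent - g$v[1]) / dv
    ok_i <- fi >= 0 & fi <= nu - 1
    ok_j <- fj >= 0 & fj <= nv - 1
    i0 <- pmin(pmax(floor(fi), 0), nu - 2); ti <- fi - i0
    j0 <- pmin(pmax(floor(fj), 0), nv - 2); tj <- fj - j0
    V <- map$values
    vals <- outer(1 - ti, 1 - tj) * V[i0 + 1, j0 + 1] +
      outer(ti, 1 - tj) * V[i0 + 2, j0 + 1] +
      outer(1 - ti, tj) * V[i0 + 1, j0 + 2] +
      outer(ti, tj) * V[i0 + 2, j0 + 2]
    neg <- vals < 0
    neg[!ok_i, ] <- FALSE
    neg[, !ok_j] <- FALSE
    pix[neg] <- style$neg_shade
  }
  if (style$line) {
    for (p in contours$polylines) {
      px <- plane_to_pixel(p[, 1], p[, 2])
      pix <- rasterize_polyline(pix, px$row, px$col, style$line_width,
                                style$line_shade)
    }
  }
  if (style$atom_marks) {
    for (i in seq_len(nrow(map$atom_marks))) {
      px <- plane_to_pixel(map$atom_marks$u[i], map$atom_marks$v[i])
      pix <- rasterize_disc(pix, px$row, px$col, style$mark_radius,
                            style$mark_shade)
    }
  }
  structure(list(pixels = pix, width = RENDER_W, height = RENDER_H,
                 provenance = list(frame_id = style$frame_id, cropped = FALSE,
                                   px_per_bohr = PX_PER_BOHR,
                                   u0 = CANVAS_U0, v0 = CANVAS_V0)),
            class = "rendered_map")
}

#' Crop a rendered map to the carbonyl-only 550 x 720 image
#'
#' The crop window keeps the full 720-pixel height and is horizontally
#' anchored so the C-O midpoint column sits at a fixed offset from the
#' window's left edge; it must contain the C and O marks and exclude the
#' nucleophile mark.
#'
#' @param image an uncropped 960 x 720 `rendered_map`.
#' @param map the `scalar_field_map` it was rendered from (for atom marks).
#' @return a cropped `rendered_map` of width 550.
#' @export
crop_carbonyl <- function(image, map) {
  stopifnot(inherits(image, "rendered_map"), inherits(map, "scalar_field_map"))
  if (isTRUE(image$provenance$cropped))
    stop_lapnet("image is already cropped", class = "lapnet_crop")
  if (image$width != RENDER_W || image$height != RENDER_H)
    stop_lapnet("crop_carbonyl expects a full ", RENDER_W, " x ", RENDER_H,
                " render", class = "lapnet_crop")
  marks <- map$atom_marks
  px <- plane_to_pixel(marks$u, marks$v)
  cols <- stats::setNames(px$col, marks$atom)
  x_mid <- (cols[["C"]] + cols[["O"]]) / 2
  left <- as.integer(round(x_mid - CROP_ANCHOR_PX))
  right <- left + CROP_W - 1L
  if (left < 1L || right > RENDER_W)
    stop_lapnet("crop window [", left, ", ", right, "] falls outside the ",
                "canvas (C-O midpoint column ", round(x_mid, 1), ")",
                class = "lapnet_crop")
  if (cols[["C"]] < left || cols[["C"]] > right ||
      cols[["O"]] < left || cols[["O"]] > right)
    stop_lapnet("carbonyl marks outside the crop window (C col ",
                round(cols[["C"]], 1), ", O col ", round(cols[["O"]], 1),
                ", window [", left, ", ", right, "])", class = "lapnet_crop")
  if (cols[["Nu"]] >= left && cols[["Nu"]] <= right)
    stop_lapnet("nucleophile mark (col ", round(cols[["Nu"]], 1),
                ") inside the crop window [", left, ", ", right, "]",
                class = "lapnet_crop")
  prov <- image$provenance
  prov$cropped <- TRUE
  prov$crop_left <- left
  structure(list(pixels = image$pixels[, left:right, drop = FALSE],
                 width = CROP_W, height = RENDER_H, provenance = prov),
            class = "rendered_map")
}

#' @export
print.rendered_map <- function(x, ...) {
  cat("rendered_map:", x$width, "x", x$height,
      if (isTRUE(x$provenance$cropped)) "(cropped)" else "(full)", "\n")
  invisible(x)
}

#' Downscale an image by integer block averaging
#'
#' @param x a `rendered_map` or a grayscale pixel matrix.
#' @param factor integer downscale factor; both image dimensions must be
#'   divisible by it.
#' @return a smaller pixel matrix.
#' @export
downscale_image <- function(x, factor) {
  pix <- if (inherits(x, "rendered_map")) x$pixels else x
  factor <- as.integer(factor)
  if (factor == 1L) return(pix)
  h <- nrow(pix); w <- ncol(pix)
  if (h %% factor != 0L || w %% factor != 0L)
    stop_lapnet("image dimensions ", h, " x ", w, " not divisible by ", factor,
                class = "lapnet_validation")
  Rh <- matrix(0, h, h %/% factor)
  Rh[cbind(seq_len(h), rep(seq_len(h %/% factor), each = factor))] <- 1 / factor
  Rw <- matrix(0, w, w %/% factor)
  Rw[cbind(seq_len(w), rep(seq_len(w %/% factor), each = factor))] <- 1 / factor
  crossprod(Rh, pix %*% Rw)
}

#' Write a rendered map as an 8-bit grayscale PNG
#' @param image a `rendered_map`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rendered_png <- function(image, path) {
  stopifnot(inherits(image, "rendered_map"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' Read a PNG as a grayscale pixel matrix
#' @param path path to a PNG file.
#' @return matrix of grayscale values in `[0, 1]`.
#' @export
read_png_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Write the sidecar JSON accompanying a rendered map
#'
#' Records plane metadata, atom marks and render provenance next to the PNG.
#'
#' @param image a `rendered_map`.
#' @param map the source `scalar_field_map`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_map_sidecar <- function(image, map, path) {
  meta <- list(field_kind = map$field_kind,
               grid = list(n_u = map$plane$n_u, n_v = map$plane$n_v,
                           extent_u = map$plane$extent_u,
                           extent_v = map$plane$extent_v),
               atom_marks = map$atom_marks,
               provenance = image$provenance)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
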