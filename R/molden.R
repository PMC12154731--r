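## Molden file reader/writer for closed-shell s/p/d Gaussian wavefunctions.
##
## Supported sections: [Atoms] (Angs or AU), [GTO], [MO], and the [5D]
## family of flags switching d shells to the 5-component spherical set.
## Internally everything is expanded to Cartesian components and shells are
## renormalized to unit basis-function self-overlap, so the reader is
## idempotent with the writer.

ELEMENT_NUMBERS <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                     O = 8, F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13,
                     Si = 14, P = 15, S = 16, Cl = 17, Ar = 18, K = 19,
                     Ca = 20, Zn = 30, Se = 34, Br = 35, Kr = 36)

molden_num <- function(x) as.numeric(gsub("[dD]", "e", x))

parse_fail <- function(section, line_no, msg) {
  stop_lapnet("Molden parse error in [", section, "] at line ", line_no,
              ": ", msg, class = "lapnet_parse")
}

#' Read a Molden wavefunction file
#'
#' Parses the `[Atoms]`, `[GTO]` and `[MO]` sections of a Molden file into a
#' [wavefunction()]. Coordinates are converted to bohr regardless of the
#' declared unit; spherical (`[5D]`) d shells are expanded to the Cartesian
#' 6-component set; shells are renormalized on load. Only closed-shell files
#' with a single (alpha) MO block and angular momenta up to d are supported.
#'
#' @param path path to a Molden file.
#' @return a [wavefunction()].
#' @export
read_molden <- function(path) {
  if (!file.exists(path))
    stop_lapnet("file not found: ", path, class = "lapnet_io")
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^\\s*\\[", lines)
  headers <- which(is_header)
  if (length(headers) == 0L)
    stop_lapnet("not a Molden file (no [section] headers): ", path,
                class = "lapnet_parse")
  header_name <- tolower(sub("^\\s*\\[([^]]+)\\].*$", "\\1", lines[headers]))
  section_of <- function(name) {
    hit <- which(header_name == name)
    if (length(hit) == 0L) return(NULL)
    start <- headers[hit[1]]
    next_h <- headers[headers > start]
    end <- if (length(next_h)) next_h[1] - 1L else length(lines)
    list(start = start, body = if (end > start) (start + 1L):end else integer(0))
  }

  for (need in c("atoms", "gto", "mo"))
    if (is.null(section_of(need)))
      stop_lapnet("Molden file lacks required [", need, "] section: ", path,
                  class = "lapnet_parse")

  spherical_d <- any(header_name %in% c("5d", "5d7f", "5d10f"))

  ## --- [Atoms] ---------------------------------------------------------
  sec <- section_of("atoms")
  unit_tag <- toupper(sub("^\\s*\\[[^]]+\\]\\s*\\(?([A-Za-z]*)\\)?.*$", "\\1",
                          lines[sec$start]))
  to_bohr <- if (unit_tag %in% c("ANGS", "ANGSTROM")) BOHR_PER_ANGSTROM else 1
  atom_rows <- list()
  for (i in sec$body) {
    ln <- trimws(lines[i])
    if (ln == "") next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 6)
      parse_fail("Atoms", i, "expected 'element index number x y z'")
    xyz <- molden_num(tok[4:6])
    if (any(is.na(xyz))) parse_fail("Atoms", i, "non-numeric coordinates")
    atom_rows[[length(atom_rows) + 1L]] <-
      data.frame(element = tok[1], index = as.integer(tok[2]),
                 x = xyz[1] * to_bohr, y = xyz[2] * to_bohr,
                 z = xyz[3] * to_bohr, stringsAsFactors = FALSE)
  }
  if (length(atom_rows) == 0L) parse_fail("Atoms", sec$start, "no atoms")
  atoms <- do.call(rbind, atom_rows)

  ## --- [GTO] -----------------------------------------------------------
  sec <- section_of("gto")
  shells <- list()
  i <- 1L
  body <- sec$body
  while (i <= length(body)) {
    ln <- trimws(lines[body[i]])
    if (ln == "") { i <- i + 1L; next }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.integer(tok[1]))))
      parse_fail("GTO", body[i], "expected atom index starting a GTO block")
    atom_idx <- as.integer(tok[1])
    i <- i + 1L
    # shells until blank line or end of section
    while (i <= length(body) && trimws(lines[body[i]]) != "") {
      tok <- strsplit(trimws(lines[body[i]]), "\\s+")[[1]]
      l <- tolower(tok[1])
      if (l %in% c("f", "g", "h", "sp"))
        stop_lapnet("unsupported angular momentum '", l, "' in [GTO] at line ",
                    body[i], class = "lapnet_unsupported")
      if (!l %in% c("s", "p", "d"))
        parse_fail("GTO", body[i], paste0("expected shell type, got '", l, "'"))
      nprim <- suppressWarnings(as.integer(tok[2]))
      if (is.na(nprim) || nprim < 1)
        parse_fail("GTO", body[i], "invalid primitive count")
      if (i + nprim > length(body))
        parse_fail("GTO", body[i], "truncated shell block")
      prim <- matrix(NA_real_, nprim, 2)
      for (p in seq_len(nprim)) {
        ptok <- strsplit(trimws(lines[body[i + p]]), "\\s+")[[1]]
        if (length(ptok) < 2)
          parse_fail("GTO", body[i + p], "expected 'exponent coefficient'")
        prim[p, ] <- molden_num(ptok[1:2])
      }
      if (any(is.na(prim))) parse_fail("GTO", body[i], "non-numeric primitive")
      shells[[length(shells) + 1L]] <-
        basis_shell(atom_idx, l, prim[, 1], prim[, 2],
                    cartesian_d = !(l == "d" && spherical_d))
      i <- i + nprim + 1L
    }
  }
  if (length(shells) == 0L) parse_fail("GTO", sec$start, "no shells")

  file_dims <- vapply(shells, function(s)
    if (s$l == "d" && !s$cartesian_d) 5L else n_cartesian(s$l), integer(1))
  n_file_basis <- sum(file_dims)

  ## --- [MO] ------------------------------------------------------------
  sec <- section_of("mo")
  occs <- numeric(0)
  coef_rows <- list()
  cur_coef <- NULL
  cur_occ <- NA_real_
  flush_mo <- function(line_no) {
    if (is.null(cur_coef)) return(invisible())
    if (length(cur_coef) != n_file_basis)
      parse_fail("MO", line_no,
                 paste0("MO has ", length(cur_coef), " coefficients but the ",
                        "basis has ", n_file_basis, " functions"))
    if (is.na(cur_occ)) parse_fail("MO", line_no, "MO lacks Occup=")
    coef_rows[[length(coef_rows) + 1L]] <<- cur_coef
    occs[length(occs) + 1L] <<- cur_occ
    cur_coef <<- NULL
    cur_occ <<- NA_real_
  }
  for (i in sec$body) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(sub("\\s*=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!is.null(cur_coef)) flush_mo(i)
      if (key == "occup") {
        cur_occ <- molden_num(val)
        if (is.na(cur_occ)) parse_fail("MO", i, "non-numeric Occup")
      } else if (key == "spin" && tolower(val) != "alpha") {
        stop_lapnet("only closed-shell (single alpha MO block) Molden files ",
                    "are supported; found Spin=", val, " at line ", i,
                    class = "lapnet_unsupported")
      }
    } else {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) < 2) parse_fail("MO", i, "expected 'index coefficient'")
      j <- suppressWarnings(as.integer(tok[1]))
      v <- molden_num(tok[2])
      if (is.na(j) || is.na(v)) parse_fail("MO", i, "non-numeric coefficient row")
      if (is.null(cur_coef)) cur_coef <- numeric(n_file_basis)
      if (j < 1 || j > n_file_basis)
        parse_fail("MO", i, paste0("coefficient index ", j, " outside basis ",
                                   "dimension ", n_file_basis))
      cur_coef[j] <- v
    }
  }
  flush_mo(sec$body[length(sec$body)])
  if (length(coef_rows) == 0L) parse_fail("MO", sec$start, "no molecular orbitals")
  mo_file <- do.call(rbind, coef_rows)

  ## expand spherical d blocks to Cartesian
  Tsph <- spherical_d_to_cartesian()
  blocks <- list()
  col <- 1L
  for (k in seq_along(shells)) {
    w <- file_dims[k]
    block <- mo_file[, col:(col + w - 1L), drop = FALSE]
    if (shells[[k]]$l == "d" && !shells[[k]]$cartesian_d) {
      block <- block %*% Tsph
      shells[[k]]$cartesian_d <- TRUE
    }
    blocks[[k]] <- block
    col <- col + w
  }
  mo_cart <- do.call(cbind, blocks)

  wavefunction(atoms, shells, mo_cart, occs)
}

#' Write a wavefunction to a Molden file
#'
#' Emits `[Atoms]` in atomic units and Cartesian d components (no `[5D]`
#' flag). The emitted file round-trips through [read_molden()] to a
#' numerically identical wavefunction.
#'
#' @param wfn a valid [wavefunction()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_molden <- function(wfn, path) {
  if (!inherits(wfn, "wavefunction"))
    stop_lapnet("write_molden expects a wavefunction object",
                class = "lapnet_validation")
  # re-validate all invariants before any write
  wavefunction(wfn$atoms, wfn$shells, wfn$mo_coefficients, wfn$occupations,
               renormalize = FALSE)
  num <- function(x) sprintf("% .16e", x)
  out <- c("[Molden Format]", "[Title]", " written by lapnet", "[Atoms] AU")
  for (i in seq_len(nrow(wfn$atoms))) {
    a <- wfn$atoms[i, ]
    z <- unname(ELEMENT_NUMBERS[a$element])
    if (is.na(z)) z <- 0
    out <- c(out, sprintf("%-3s %4d %4d %s %s %s", a$element, a$index, z,
                          num(a$x), num(a$y), num(a$z)))
  }
  out <- c(out, "[GTO]")
  by_atom <- split(seq_along(wfn$shells),
                   vapply(wfn$shells, `[[`, integer(1), "atom"))
  for (atom_idx in wfn$atoms$index) {
    out <- c(out, sprintf("%4d 0", atom_idx))
    for (k in by_atom[[as.character(atom_idx)]]) {
      sh <- wfn$shells[[k]]
      out <- c(out, sprintf(" %s %4d 1.00", sh$l, length(sh$exponents)))
      out <- c(out, paste0("  ", num(sh$exponents), " ", num(sh$coefficients)))
    }
    out <- c(out, "")
  }
  out <- c(out, "[MO]")
  for (m in seq_len(nrow(wfn$mo_coefficients))) {
    out <- c(out, " Sym= A", sprintf(" Ene= %d", m), " Spin= Alpha",
             sprintf(" Occup= %s", num(wfn$occupations[m])),
             sprintf("%6d %s", seq_len(ncol(wfn$mo_coefficients)),
                     num(wfn$mo_coefficients[m, ])))
  }
  writeLines(out, path)
  invisible(path)
}
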