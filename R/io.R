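#' Read and write two-column G(r) files
#'
#' Whitespace-separated r (angstrom) and G(r) columns.  Comment lines
#' start with `#`; header blocks from common PDF reduction tools (lines
#' that do not parse as two numbers) are skipped.
#'
#' @param path file path
#' @param qmin,qmax Q-range metadata attached to the returned grid
#' @return a [pdf_grid()]
#' @export
read_gr <- function(path, qmin = 0.5, qmax = 25.6) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parsed <- lapply(strsplit(trimws(lines), "\\s+"), function(x) suppressWarnings(as.numeric(x)))
  ok <- vapply(parsed, function(x) length(x) >= 2 && all(is.finite(x[1:2])), logical(1))
  if (!any(ok)) stop("no numeric two-column data in ", path)
  m <- do.call(rbind, lapply(parsed[ok], function(x) x[1:2]))
  pdf_grid(m[, 1], m[, 2], qmin = qmin, qmax = qmax)
}

#' @rdname read_gr
#' @param grid a [pdf_grid()]
#' @export
write_gr <- function(grid, path) {
  stopifnot(inherits(grid, "pdf_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# r (Angstrom)   G(r) (1/Angstrom^2)",
               sprintf("# Qmin = %g 1/Angstrom, Qmax = %g 1/Angstrom",
                       grid$qmin, grid$qmax)), con)
  writeLines(sprintf("%.6f %.10e", grid$r, grid$g), con)
  invisible(path)
}

#' Read and write two-column powder patterns
#'
#' `.xy`-style files: two-theta in degrees and intensity, whitespace
#' separated, `#` comments.
#'
#' @param path file path
#' @return data.frame with columns `tth` (degrees) and `intensity`
#' @export
read_xy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, comment.char = "#", col.names = c("tth", "intensity"),
                   colClasses = "numeric")
  if (nrow(df) == 0) stop("empty pattern: ", path)
  df
}

#' @rdname read_xy
#' @param pattern data.frame with columns `tth`, `intensity`
#' @export
write_xy <- function(pattern, path) {
  stopifnot(all(c("tth", "intensity") %in% names(pattern)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# two-theta (degrees)   intensity (arbitrary)", con)
  writeLines(sprintf("%.5f %.8e", pattern$tth, pattern$intensity), con)
  invisible(path)
}

#' Read and write FT-IR spectra
#'
#' Two-column CSV or whitespace text: wavenumber (1/cm) and absorbance.
#'
#' @param path file path
#' @return an [ir_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 20, warn = FALSE)
  sep <- if (any(grepl(",", first))) "," else ""
  df <- read.table(path, comment.char = "#", sep = sep,
                   col.names = c("wavenumber", "absorbance"),
                   colClasses = "numeric")
  ir_spectrum(df$wavenumber, df$absorbance)
}

#' @rdname read_spectrum
#' @param spectrum an [ir_spectrum()]
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavenumber (1/cm), absorbance", con)
  writeLines(sprintf("%.4f,%.8e", spectrum$wavenumber, spectrum$absorbance), con)
  invisible(path)
}

#' Write a structure as a P1 CIF
#'
#' Minimal crystallographic information file: cell block plus an
#' `atom_site` loop with label, type symbol, fractional coordinates,
#' occupancy and isotropic B.
#'
#' @param structure a `p1_structure`
#' @param path output path
#' @param data_name CIF data block name
#' @export
write_cif <- function(structure, path, data_name = "apatitepdf") {
  s <- structure$sites
  cell <- structure$cell
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("data_", data_name),
    "_symmetry_space_group_name_H-M   'P 1'",
    "_symmetry_Int_Tables_number      1",
    sprintf("_cell_length_a     %.6f", cell$a),
    sprintf("_cell_length_b     %.6f", cell$b),
    sprintf("_cell_length_c     %.6f", cell$c),
    sprintf("_cell_angle_alpha  %.4f", cell$alpha),
    sprintf("_cell_angle_beta   %.4f", cell$beta),
    sprintf("_cell_angle_gamma  %.4f", cell$gamma),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_B_iso_or_equiv",
    sprintf("%-8s %-2s %10.6f %10.6f %10.6f %8.5f %8.4f",
            s$label, s$species, s$x, s$y, s$z, s$occ, s$b)), con)
  invisible(path)
}

#' Read a P1 CIF written by [write_cif()] (or any CIF carrying a cell and
#' a plain `atom_site` loop)
#'
#' Parses `_cell_length_*`/`_cell_angle_*` tags and the `atom_site` loop
#' columns label, type symbol, fract x/y/z, occupancy and B (occupancy
#' and B default to 1 when absent).  Parenthesised standard uncertainties
#' are stripped.
#'
#' @param path CIF file path
#' @return a `p1_structure`
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  num <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) stop("CIF tag not found: ", tag)
    as.numeric(gsub("\\(.*\\)", "", strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
  }
  cell <- unit_cell(num("_cell_length_a"), num("_cell_length_b"),
                    num("_cell_length_c"), num("_cell_angle_alpha"),
                    num("_cell_angle_beta"), num("_cell_angle_gamma"))

  # locate the atom_site loop
  loop_starts <- grep("^\\s*loop_", lines)
  site_loop <- NULL
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (any(grepl("^_atom_site_fract_x", tags))) {
      site_loop <- list(tags = tags, body_start = i)
      break
    }
  }
  if (is.null(site_loop)) stop("no atom_site loop in ", path)
  tags <- site_loop$tags
  i <- site_loop$body_start
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^(_|loop_|data_|#)", ln)) break
    rows[[length(rows) + 1]] <- strsplit(ln, "\\s+")[[1]]
    i <- i + 1
  }
  get_col <- function(tag, default = NULL) {
    j <- grep(paste0("^", tag, "$"), tags)
    if (length(j) == 0) {
      if (is.null(default)) stop("atom_site loop lacks ", tag)
      return(rep(default, length(rows)))
    }
    vapply(rows, `[[`, character(1), j)
  }
  numcol <- function(x) as.numeric(gsub("\\(.*\\)", "", x))
  label <- get_col("_atom_site_label")
  species <- get_col("_atom_site_type_symbol", default = NA)
  if (all(is.na(species))) species <- gsub("[0-9_].*$", "", label)
  sites <- data.frame(
    label = label, species = species,
    site = gsub("_[0-9]+$", "", label),
    x = wrap_frac(numcol(get_col("_atom_site_fract_x"))),
    y = wrap_frac(numcol(get_col("_atom_site_fract_y"))),
    z = wrap_frac(numcol(get_col("_atom_site_fract_z"))),
    occ = numcol(get_col("_atom_site_occupancy", default = "1")),
    b = numcol(get_col("_atom_site_B_iso_or_equiv", default = "1")),
    stringsAsFactors = FALSE)
  structure(list(cell = cell, sites = sites,
                 provenance = list(kind = "cif", path = path)),
            class = "p1_structure")
}
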