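#' Run code with a local, seeded RNG
#'
#' Every generator is a pure function of (spec, seed): the global RNG
#' state is saved and restored.
#'
#' @param seed integer seed
#' @param code expression
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed)) stop("a seed is mandatory for stochastic draws")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic PDF observation with known truth
#'
#' Evaluates the forward model at the truth parameters and adds Gaussian
#' noise of standard deviation `noise * max(abs(G))`.
#'
#' @param params a [parameter_set()] holding the truth values
#' @param grid a [pdf_grid()] to evaluate on
#' @param noise noise level as a fraction of the curve maximum (>= 0)
#' @param seed integer seed (required when `noise > 0`)
#' @param model model builder output; defaults to
#'   [ha_pdf_model()] on `grid`
#' @return list: `pdf` (the noisy [pdf_grid()]), `truth` (named value
#'   vector), `noise_sd` (absolute noise standard deviation)
#' @export
make_pdf_sample <- function(params, grid, noise = 0, seed = NULL,
                            model = ha_pdf_model(grid)) {
  stopifnot(inherits(params, "parameter_set"), noise >= 0)
  if (noise > 0 && (is.null(seed) || !is.finite(seed)))
    stop("a seed is mandatory for noisy draws")
  v <- param_values(params)
  clean <- model(v)
  sdev <- noise * max(abs(clean$g))
  g <- if (noise > 0) {
    with_seed(seed, clean$g + rnorm(length(clean$g), 0, sdev))
  } else clean$g
  list(pdf = pdf_grid(clean$r, g, qmin = grid$qmin, qmax = grid$qmax),
       truth = v, noise_sd = sdev)
}

#' Synthetic ATR FT-IR spectrum of carbonated apatite
#'
#' Pseudo-Voigt sum emulating the phosphate nu1/nu3 envelope
#' (bands near 962, 1030 and 1090 1/cm) and the nu2 carbonate triplet at
#' fixed centres, on a sloped baseline with additive noise.  The total
#' carbonate triplet area is set so that the nu2CO3 : nu1nu3PO4 net-area
#' ratio equals `wtpc / ratio_slope`, i.e. concentration is linear in the
#' ratio by construction; the triplet area is split across the three
#' components at fixed proportions.
#'
#' @param wtpc carbonate content of the emulated sample, wt%
#' @param noise noise level, fraction of the spectrum maximum
#' @param seed integer seed (required when `noise > 0`)
#' @param ratio_slope wt% per unit area ratio of the emulation (default
#'   50)
#' @param proportions area split across the 878/873/866 components
#' @param grid wavenumber grid, 1/cm
#' @param baseline intercept and slope (per 1/cm) of the linear baseline
#' @return an [ir_spectrum()]
#' @export
make_ir_spectrum <- function(wtpc, noise = 0, seed = NULL, ratio_slope = 50,
                             proportions = c(0.3, 0.5, 0.2),
                             grid = seq(700, 1400, by = 2),
                             baseline = c(0.02, 1e-5)) {
  stopifnot(wtpc >= 0, noise >= 0, length(proportions) == 3)
  proportions <- proportions / sum(proportions)
  # pure-Gaussian phosphate bands: no Lorentzian tails leak into the
  # 840-910 carbonate window, so the emulated area ratio is exactly
  # proportional to wtpc
  po4 <- 1.00 * pseudo_voigt(grid, 1030, 55, 0) +
         0.55 * pseudo_voigt(grid, 1090, 45, 0) +
         0.15 * pseudo_voigt(grid, 962, 14, 0)
  # net phosphate area as the analysis will measure it
  po4_area <- phosphate_area(ir_spectrum(grid, po4), 900, 1200)
  co3_total <- po4_area * wtpc / ratio_slope
  # Gaussian-limit components for the same reason: Lorentzian tails from
  # the triplet would otherwise leak into the phosphate window
  centres <- c(878, 873, 866)
  fwhm <- c(6, 7, 5.5); eta <- c(0, 0, 0)
  amp <- co3_total * proportions / pseudo_voigt_area(1, fwhm, eta)
  co3 <- amp[1] * pseudo_voigt(grid, centres[1], fwhm[1], eta[1]) +
         amp[2] * pseudo_voigt(grid, centres[2], fwhm[2], eta[2]) +
         amp[3] * pseudo_voigt(grid, centres[3], fwhm[3], eta[3])
  y <- po4 + co3 + baseline[1] + baseline[2] * grid
  if (noise > 0) y <- with_seed(seed, y + rnorm(length(y), 0, noise * max(y)))
  ir_spectrum(grid, y)
}

#' Synthetic 002/030 diffraction window with breadths set by crystallite
#' size
#'
#' Two split pseudo-Voigt Bragg maxima (002 near 25.9 and 030 near 32.9
#' degrees two-theta for apatite with Cu K-alpha) on a linear background.
#' Peak breadths follow the Scherrer relation at the given coherence
#' lengths, making the size pipeline self-consistent by construction.
#'
#' @param cl002,cl030 coherence lengths of the two reflections, angstrom
#' @param a,c lattice parameters used to place the maxima, angstrom
#' @param lambda wavelength, angstrom
#' @param K Scherrer constant used in the emulation
#' @param noise noise level, fraction of max intensity
#' @param seed integer seed (required when `noise > 0`)
#' @param step two-theta step, degrees
#' @return data.frame pattern (`tth`, `intensity`) spanning 23-35 degrees
#'   with attributes `window_002` and `window_030`
#' @export
make_peak_pattern <- function(cl002, cl030, a = 9.4227, c = 6.8886,
                              lambda = 1.5406, K = 0.9, noise = 0,
                              seed = NULL, step = 0.01) {
  stopifnot(cl002 > 0, cl030 > 0)
  d002 <- c / 2
  d030 <- sqrt(1 / ((4 / 3) * 9 / a^2))
  tth <- function(d) 2 * asin(lambda / (2 * d)) * 180 / pi
  t002 <- tth(d002); t030 <- tth(d030)
  fw <- function(cl, tthc) {
    beta <- K * lambda / (cl * cos(tthc / 2 * pi / 180))  # radians
    beta * 180 / pi
  }
  x <- seq(23, 35, by = step)
  y <- 100 * split_pseudo_voigt(x, t002, fw(cl002, t002), fw(cl002, t002), 0.4, 0.4) +
       80 * split_pseudo_voigt(x, t030, fw(cl030, t030), fw(cl030, t030), 0.4, 0.4) +
       5 + 0.1 * (x - 23)
  if (noise > 0) y <- with_seed(seed, y + rnorm(length(y), 0, noise * max(y)))
  out <- data.frame(tth = x, intensity = y)
  attr(out, "window_002") <- c(t002 - 1.4, t002 + 1.4)
  attr(out, "window_030") <- c(t030 - 1.4, t030 + 1.4)
  out
}

#' Cohort specification
#'
#' @param n_samples number of samples (>= 2)
#' @param group label: `"low-T"` (nanocrystalline, room-temperature
#'   synthesis) or `"high-T"` (crystalline, 80-90 C synthesis)
#' @param wtpc_range carbonate range, wt%, within `[0, 9]`
#' @param t_range sheet-thickness range, angstrom, within `[15, 500]`
#'   (defaults: 20-40 for low-T platy nanocrystals, 150-400 for high-T)
#' @param noise noise fraction for the generated observations
#' @param seed integer seed (mandatory)
#' @export
cohort_spec <- function(n_samples, group = c("low-T", "high-T"),
                        wtpc_range = NULL, t_range = NULL,
                        noise = 0.01, seed) {
  group <- match.arg(group)
  if (n_samples < 2) stop("a cohort needs at least 2 samples")
  if (is.null(wtpc_range)) wtpc_range <- if (group == "low-T") c(1.96, 7.98) else c(1.24, 8.12)
  if (is.null(t_range)) t_range <- if (group == "low-T") c(20, 40) else c(150, 400)
  if (any(wtpc_range < 0) || any(wtpc_range > 9)) stop("wtpc_range must lie in [0, 9]")
  if (any(t_range < 15) || any(t_range > 500)) stop("t_range must lie in [15, 500] A")
  if (missing(seed)) stop("seed is mandatory")
  structure(list(n_samples = n_samples, group = group,
                 wtpc_range = wtpc_range, t_range = t_range,
                 noise = noise, seed = seed), class = "cohort_spec")
}

# typical refined-parameter scatter used by the measured-parameter
# emulation (standard deviations on each refined quantity)
.measured_scatter <- c(a = 0.002, c = 0.002, P_x = 0.002, P_y = 0.002,
                       Ca1_z = 0.002, Ca2_x = 0.002, Ca2_y = 0.002,
                       OH_z = 0.003, zrot = 1.0,
                       d_PO1 = 0.010, d_PO2 = 0.010, d_PO3 = 0.010,
                       ang_O1PO2 = 0.8, ang_O1PO3 = 0.8,
                       tors_O3a = 1.5, tors_O3b = 1.5,
                       occ_P = 0.015, occ_O1 = 0.02, occ_O2 = 0.02,
                       occ_O3 = 0.02, occ_Ca1 = 0.02, occ_Ca2 = 0.02,
                       occ_OH = 0.03, t = 2.0)

#' Generate a multi-sample cohort with planted composition-structure
#' relationships
#'
#' For each sample: draw a carbonate content uniformly in the spec range,
#' derive the charge-balanced expected occupancies (so true P occupancy
#' falls linearly with substitution), draw a sheet thickness, and emit
#' consistent observations: optionally a PDF (forward model plus noise),
#' an FT-IR spectrum whose area ratio encodes the carbonate content, and
#' an 002/030 peak pattern whose breadths follow the thickness.  A
#' `measured` parameter table emulates refinement output as truth plus
#' typical per-parameter scatter and feeds the cohort-level correlation
#' reports; full per-sample refinement is available through [refine()] on
#' the emitted PDFs.
#'
#' @param spec a [cohort_spec()]
#' @param make_pdf generate per-sample PDFs (the slowest observation)
#' @param grid PDF grid used when `make_pdf = TRUE`
#' @return object of class `cohort`: list with `spec`, `samples` (each:
#'   `wtpc`, `t`, `truth` parameter vector, `ir`, `pattern`, optionally
#'   `pdf`), `truth_table` and `measured` data.frames
#' @export
make_cohort <- function(spec, make_pdf = FALSE,
                        grid = pdf_grid_range(1, 30, 0.05)) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    wtpc <- runif(n, spec$wtpc_range[1], spec$wtpc_range[2])
    tval <- runif(n, spec$t_range[1], spec$t_range[2])
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      comp <- expected_occupancies(wtpc[i])
      occ <- comp$occupancies
      p <- ha_parameter_set(t = tval[i])
      for (nm in names(occ)) p <- set_param(p, nm, value = occ[[nm]])
      truth <- param_values(p)
      pdf <- if (make_pdf)
        make_pdf_sample(p, grid, noise = spec$noise,
                        seed = sample.int(2^31 - 1, 1))$pdf
      else NULL
      ir <- make_ir_spectrum(wtpc[i], noise = spec$noise,
                             seed = sample.int(2^31 - 1, 1))
      # Bragg coherence lengths run near tenfold the real-space sheet
      # thickness for platy nanocrystals; the 030 direction is longer still
      pattern <- make_peak_pattern(cl002 = tval[i] * 10,
                                   cl030 = tval[i] * 25,
                                   noise = spec$noise,
                                   seed = sample.int(2^31 - 1, 1))
      samples[[i]] <- list(wtpc = wtpc[i], t = tval[i], truth = truth,
                           ir = ir, pattern = pattern, pdf = pdf)
    }
    truth_table <- as.data.frame(do.call(rbind, lapply(samples, `[[`, "truth")))
    truth_table$wtpc <- wtpc
    measured <- truth_table
    for (nm in names(.measured_scatter)) {
      if (!nm %in% names(measured)) next
      measured[[nm]] <- measured[[nm]] +
        rnorm(n, 0, .measured_scatter[[nm]])
      if (grepl("^occ_", nm)) measured[[nm]] <- pmin(1, pmax(0, measured[[nm]]))
    }
    structure(list(spec = spec, samples = samples,
                   truth_table = truth_table, measured = measured),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d %s samples, %.2f-%.2f wt%% CO3, t %.0f-%.0f A, noise %.3g\n",
              x$spec$n_samples, x$spec$group,
              min(x$truth_table$wtpc), max(x$truth_table$wtpc),
              min(x$truth_table$t), max(x$truth_table$t), x$spec$noise))
  invisible(x)
}

#' Write and read ground-truth records
#'
#' Plain-text key-value serialization with full double precision (17
#' significant digits), so records round-trip exactly.
#'
#' @param truth named numeric vector
#' @param path file path
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.numeric(truth), !is.null(names(truth)))
  writeLines(c("# ground truth record",
               sprintf("%s %.17g", names(truth), truth)), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
           vapply(parts, `[[`, character(1), 1))
}
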