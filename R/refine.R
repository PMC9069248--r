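#' PDF model builders
#'
#' A model builder closes over a grid and fixed settings and returns a
#' function mapping a named parameter-value vector to a calculated
#' [pdf_grid()].  `ha_pdf_model` drives [expand_p1()] with the full
#' apatite parameterisation of [ha_parameter_set()]; `si_pdf_model` the
#' diamond-silicon standard of [si_parameter_set()].
#'
#' @param grid the [pdf_grid()] on which the model is evaluated (the
#'   observed grid)
#' @param envelope `"nanosheet"` (uses parameter `t`) or `"none"`
#' @return function of a named numeric vector returning a `pdf_grid`
#' @export
ha_pdf_model <- function(grid, envelope = c("nanosheet", "none")) {
  envelope <- match.arg(envelope)
  force(grid)
  function(v) {
    adps <- list(
      Ca = adp_model(v[["beqlo_Ca"]], max(v[["beqhi_Ca"]], v[["beqlo_Ca"]] + 1e-9),
                     v[["beq_radius"]]),
      P = adp_model(v[["beqlo_P"]], max(v[["beqhi_P"]], v[["beqlo_P"]] + 1e-9),
                    v[["beq_radius"]]),
      O = adp_model(v[["beqlo_O"]], max(v[["beqhi_O"]], v[["beqlo_O"]] + 1e-9),
                    v[["beq_radius"]]))
    st <- expand_p1(
      hexagonal_cell(v[["a"]], v[["c"]]),
      asym_coordinates(v[["P_x"]], v[["P_y"]], v[["Ca1_z"]],
                       v[["Ca2_x"]], v[["Ca2_y"]], v[["OH_z"]]),
      rigid_body_spec(v[["d_PO1"]], v[["d_PO2"]], v[["d_PO3"]],
                      v[["ang_O1PO2"]], v[["ang_O1PO3"]],
                      v[["tors_O3a"]], v[["tors_O3b"]]),
      zrot = v[["zrot"]],
      occ = occupancy_set(v[["occ_P"]], v[["occ_O1"]], v[["occ_O2"]],
                          v[["occ_O3"]], v[["occ_Ca1"]], v[["occ_Ca2"]],
                          v[["occ_OH"]]),
      adps = 1.0, check_overlap = FALSE)
    env <- if (envelope == "nanosheet")
      shape_envelope("nanosheet", t = v[["t"]], qdamp = v[["qdamp"]])
    else shape_envelope("none", qdamp = v[["qdamp"]])
    calc_gr(st, grid, adp = adps, env = env, scale = v[["scale"]])
  }
}

#' @rdname ha_pdf_model
#' @export
si_pdf_model <- function(grid) {
  force(grid)
  function(v) {
    st <- silicon_structure(a = v[["a"]])
    adps <- list(Si = adp_model(v[["beqlo_Si"]],
                                max(v[["beqhi_Si"]], v[["beqlo_Si"]] + 1e-9),
                                v[["beq_radius"]]))
    calc_gr(st, grid, adp = adps,
            env = shape_envelope("none", qdamp = v[["qdamp"]]),
            scale = v[["scale"]])
  }
}

#' Weighted residual of a fit
#'
#' `rw = sqrt(sum((G_obs - G_calc)^2) / sum(G_obs^2))`; independent of any
#' common scale applied to both curves.
#'
#' @param observed,calculated [pdf_grid()]s on identical grids
#' @export
rw_residual <- function(observed, calculated) {
  if (length(observed$r) != length(calculated$r) ||
      max(abs(observed$r - calculated$r)) > 1e-9)
    stop("observed and calculated grids must be identical")
  sqrt(sum((observed$g - calculated$g)^2) / sum(observed$g^2))
}

#' Real-space least-squares refinement
#'
#' Minimises `sum((G_obs - G_calc)^2)` over the parameters flagged
#' `refine` by bounded Levenberg-Marquardt least squares with a numerical
#' Jacobian.  Deterministic given the observed curve and the starting
#' values.  Estimated standard deviations come from the reduced
#' chi-square-scaled covariance at the optimum and are flagged as
#' approximate when any parameter converges onto a bound.
#'
#' @param observed observed [pdf_grid()]
#' @param params a [parameter_set()] with at least one refined parameter
#' @param model model function from [ha_pdf_model()]/[si_pdf_model()] (or
#'   any function of a named value vector returning a `pdf_grid` on the
#'   observed grid)
#' @param maxiter iteration cap
#' @param ftol relative sum-of-squares convergence tolerance
#' @return object of class `refinement_result`: list with `params` (the
#'   updated parameter set), `esd` (named vector, NA for fixed
#'   parameters), `rw`, `rw_initial`, `converged`, `niter`, `at_bound`,
#'   `message`
#' @export
refine <- function(observed, params, model, maxiter = 200, ftol = 1e-10) {
  stopifnot(inherits(observed, "pdf_grid"), inherits(params, "parameter_set"))
  free <- which(params$refine)
  if (length(free) == 0) stop("at least one parameter must be flagged refine")
  v0 <- param_values(params)

  resid_fn <- function(p) {
    v <- v0
    v[params$name[free]] <- p
    gc <- model(v)
    res <- observed$g - gc$g
    if (any(!is.finite(res)))
      stop("non-finite residual during refinement (parameters: ",
           paste(sprintf("%s=%.6g", params$name[free], p), collapse = ", "), ")")
    res
  }

  rw0 <- {
    gc0 <- model(v0)
    rw_residual(observed, gc0)
  }

  fit <- minpack.lm::nls.lm(
    par = setNames(params$value[free], params$name[free]),
    lower = params$lower[free], upper = params$upper[free],
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = 1e-10))

  out <- params
  out$value[free] <- as.numeric(fit$par)
  vfin <- param_values(out)
  rw1 <- rw_residual(observed, model(vfin))

  n <- length(observed$g); p <- length(free)
  esd <- setNames(rep(NA_real_, nrow(params)), params$name)
  s2 <- fit$deviance / max(1, n - p)
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    dg <- diag(cov)
    dg[dg < 0] <- NA_real_
    esd[params$name[free]] <- sqrt(dg)
  }
  at_bound <- params$name[free][
    abs(out$value[free] - params$lower[free]) < 1e-12 |
    abs(out$value[free] - params$upper[free]) < 1e-12]

  structure(list(params = out, esd = esd, rw = rw1, rw_initial = rw0,
                 converged = fit$info %in% 1:4, niter = fit$niter,
                 at_bound = at_bound, message = fit$message),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: rw %.5f (from %.5f), %d iterations, %s\n",
              x$rw, x$rw_initial, x$niter,
              if (x$converged) "converged" else "NOT converged"))
  free <- x$params$refine
  tab <- data.frame(name = x$params$name[free],
                    value = signif(x$params$value[free], 8),
                    esd = signif(x$esd[x$params$name[free]], 3))
  print(tab, row.names = FALSE)
  if (length(x$at_bound))
    cat("  at bound:", paste(x$at_bound, collapse = ", "),
        "(esds approximate)\n")
  invisible(x)
}

#' Default refinement staging for the apatite model
#'
#' Stage order: scale and damping, then lattice, then coordinates and body
#' rotation, then rigid-body internals, then occupancies and ADPs, then
#' sheet thickness.
#'
#' @export
default_stages <- function() {
  list(c("scale", "qdamp"),
       c("a", "c"),
       c("P_x", "P_y", "Ca1_z", "Ca2_x", "Ca2_y", "OH_z", "zrot"),
       c("d_PO1", "d_PO2", "d_PO3", "ang_O1PO2", "ang_O1PO3",
         "tors_O3a", "tors_O3b"),
       c("occ_P", "occ_O1", "occ_O2", "occ_O3", "occ_Ca1", "occ_Ca2",
         "occ_OH", "beqlo_Ca", "beqhi_Ca", "beqlo_P", "beqhi_P",
         "beqlo_O", "beqhi_O", "beq_radius"),
       "t")
}

#' Staged refinement
#'
#' Runs [refine()] over ordered parameter groups, carrying refined values
#' forward.  Only parameters that are both in a stage and flagged `refine`
#' in `params` are freed in that stage; stages with no such parameters are
#' skipped.
#'
#' @inheritParams refine
#' @param stages list of character vectors of parameter names
#' @return the final [refine()] result (its `params` carry all stages'
#'   updates); the per-stage rw path is attached as attribute `rw_path`
#' @export
staged_refine <- function(observed, params, model, stages = default_stages(),
                          maxiter = 200, ftol = 1e-10) {
  unknown <- setdiff(unlist(stages), params$name)
  if (length(unknown))
    stop("stage references unknown parameter(s): ", paste(unknown, collapse = ", "))
  wanted <- params$name[params$refine]
  cur <- params
  res <- NULL
  rw_path <- numeric()
  for (stage in stages) {
    sel <- intersect(stage, wanted)
    if (length(sel) == 0) next
    res <- refine(observed, refine_only(cur, sel), model,
                  maxiter = maxiter, ftol = ftol)
    cur <- res$params
    rw_path <- c(rw_path, res$rw)
  }
  if (is.null(res)) stop("no stage contained a refined parameter")
  res$params <- refine_only(cur, wanted)
  attr(res, "rw_path") <- rw_path
  res
}
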