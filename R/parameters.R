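#' Refinable parameter sets
#'
#' A parameter set is a data.frame with columns `name`, `value`, `refine`
#' (logical), `lower`, `upper`.  Bounds must be finite for refined
#' parameters.  [ha_parameter_set()] builds the full apatite-model table
#' (lattice, asymmetric coordinates, rigid body, occupancies, ADP model,
#' nanosheet thickness, instrumental damping and scale);
#' [si_parameter_set()] the silicon-standard table used for damping
#' calibration.
#'
#' @param df data.frame with at least `name` and `value`; missing `refine`
#'   defaults to FALSE, missing bounds to the widest physical range
#' @return object of class `parameter_set` (a data.frame)
#' @export
parameter_set <- function(df) {
  stopifnot(is.data.frame(df), all(c("name", "value") %in% names(df)))
  if (is.null(df$refine)) df$refine <- FALSE
  if (is.null(df$lower)) df$lower <- -Inf
  if (is.null(df$upper)) df$upper <- Inf
  if (anyDuplicated(df$name)) stop("duplicate parameter names")
  if (any(df$value < df$lower | df$value > df$upper))
    stop("parameter values must lie within their bounds")
  bad <- df$refine & (!is.finite(df$lower) | !is.finite(df$upper))
  if (any(bad))
    stop("refined parameters need finite bounds: ", paste(df$name[bad], collapse = ", "))
  class(df) <- c("parameter_set", "data.frame")
  df
}

.pdef <- function(name, value, refine = FALSE, lower = -Inf, upper = Inf) {
  data.frame(name = name, value = value, refine = refine,
             lower = lower, upper = upper, stringsAsFactors = FALSE)
}

#' @rdname parameter_set
#' @param t sheet thickness start value, angstrom
#' @param qdamp instrumental damping start value, 1/angstrom
#' @export
ha_parameter_set <- function(t = 30, qdamp = 0.03) {
  co <- asym_coordinates()
  rb <- ha_rigid_body_spec()
  rows <- rbind(
    .pdef("a", 9.4227, lower = 9.0, upper = 9.9),
    .pdef("c", 6.8886, lower = 6.5, upper = 7.3),
    .pdef("P_x", co$P_x, lower = 0.30, upper = 0.50),
    .pdef("P_y", co$P_y, lower = 0.27, upper = 0.47),
    .pdef("Ca1_z", co$Ca1_z, lower = -0.1, upper = 0.1),
    .pdef("Ca2_x", co$Ca2_x, lower = 0.15, upper = 0.35),
    .pdef("Ca2_y", co$Ca2_y, lower = 0.89, upper = 1.09),
    .pdef("OH_z", co$OH_z, lower = 0.05, upper = 0.30),
    .pdef("zrot", 141.95, lower = 100, upper = 180),
    .pdef("d_PO1", rb$d_PO1, lower = 1.3, upper = 1.8),
    .pdef("d_PO2", rb$d_PO2, lower = 1.3, upper = 1.8),
    .pdef("d_PO3", rb$d_PO3, lower = 1.3, upper = 1.8),
    .pdef("ang_O1PO2", rb$ang_O1PO2, lower = 90, upper = 135),
    .pdef("ang_O1PO3", rb$ang_O1PO3, lower = 90, upper = 135),
    .pdef("tors_O3a", rb$tors_O3a, lower = 90, upper = 150),
    .pdef("tors_O3b", rb$tors_O3b, lower = 210, upper = 270),
    .pdef("occ_P", 1, lower = 0, upper = 1),
    .pdef("occ_O1", 1, lower = 0, upper = 1),
    .pdef("occ_O2", 1, lower = 0, upper = 1),
    .pdef("occ_O3", 1, lower = 0, upper = 1),
    .pdef("occ_Ca1", 1, lower = 0, upper = 1),
    .pdef("occ_Ca2", 1, lower = 0, upper = 1),
    .pdef("occ_OH", 1, lower = 0, upper = 1),
    .pdef("beqlo_Ca", 0.5, lower = 0.05, upper = 4),
    .pdef("beqhi_Ca", 1.0, lower = 0.05, upper = 6),
    .pdef("beqlo_P", 0.4, lower = 0.05, upper = 4),
    .pdef("beqhi_P", 0.9, lower = 0.05, upper = 6),
    .pdef("beqlo_O", 0.6, lower = 0.05, upper = 4),
    .pdef("beqhi_O", 1.4, lower = 0.05, upper = 6),
    .pdef("beq_radius", 4, lower = 1, upper = 15),
    .pdef("t", t, lower = 5, upper = 500),
    .pdef("qdamp", qdamp, lower = 0, upper = 0.2),
    .pdef("scale", 1, lower = 0.01, upper = 100)
  )
  parameter_set(rows)
}

#' @rdname parameter_set
#' @param a silicon cubic lattice constant start value, angstrom
#' @export
si_parameter_set <- function(a = 5.4312, qdamp = 0.03) {
  rows <- rbind(
    .pdef("a", a, lower = 5.2, upper = 5.7),
    .pdef("beqlo_Si", 0.3, lower = 0.05, upper = 4),
    .pdef("beqhi_Si", 0.6, lower = 0.05, upper = 6),
    .pdef("beq_radius", 4, lower = 1, upper = 15),
    .pdef("qdamp", qdamp, lower = 0, upper = 0.2),
    .pdef("scale", 1, lower = 0.01, upper = 100)
  )
  parameter_set(rows)
}

#' @rdname parameter_set
#' @param params a `parameter_set`
#' @export
param_values <- function(params) setNames(params$value, params$name)

#' Update entries of a parameter set
#'
#' @param params a `parameter_set`
#' @param name parameter name (must exist)
#' @param value,refine,lower,upper fields to update; omitted fields are
#'   kept
#' @export
set_param <- function(params, name, value = NULL, refine = NULL,
                      lower = NULL, upper = NULL) {
  i <- match(name, params$name)
  if (anyNA(i)) stop("unknown parameter: ", paste(name[is.na(i)], collapse = ", "))
  if (!is.null(value)) params$value[i] <- value
  if (!is.null(refine)) params$refine[i] <- refine
  if (!is.null(lower)) params$lower[i] <- lower
  if (!is.null(upper)) params$upper[i] <- upper
  parameter_set(as.data.frame(params))
}

#' Flag exactly these parameters for refinement
#'
#' @param params a `parameter_set`
#' @param names character vector of parameter names to refine; all others
#'   are fixed
#' @export
refine_only <- function(params, names) {
  miss <- setdiff(names, params$name)
  if (length(miss)) stop("unknown parameter: ", paste(miss, collapse = ", "))
  params$refine <- params$name %in% names
  parameter_set(as.data.frame(params))
}

#' Read or write a parameter configuration file
#'
#' YAML with one section per parameter: `value`, `refine`, `lower`,
#' `upper`.
#'
#' @param params a `parameter_set`
#' @param path file path
#' @export
write_param_config <- function(params, path) {
  lst <- lapply(seq_len(nrow(params)), function(i)
    list(value = params$value[i], refine = params$refine[i],
         lower = params$lower[i], upper = params$upper[i]))
  names(lst) <- params$name
  yaml::write_yaml(list(parameters = lst), path)
  invisible(path)
}

#' @rdname write_param_config
#' @export
read_param_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$parameters)) stop("config has no 'parameters' section: ", path)
  rows <- do.call(rbind, lapply(names(y$parameters), function(nm) {
    p <- y$parameters[[nm]]
    .pdef(nm, p$value, isTRUE(p$refine),
          if (is.null(p$lower)) -Inf else p$lower,
          if (is.null(p$upper)) Inf else p$upper)
  }))
  parameter_set(rows)
}
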