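#' Motility parameters of a bacterial species
#'
#' Bundles the dimensional motility parameters that characterise a swimmer:
#' swimming speed, rotational diffusion, body shape, and (optionally) thermal
#' diffusivity. Canonical units throughout the package are micrometres and
#' seconds; no implicit unit conversion is performed.
#'
#' Run-and-tumble species are represented by substituting the tumble rate for
#' the rotational diffusion coefficient, a standard approximation for dilute
#' suspensions free of external forcing.
#'
#' @param swim_speed Swimming speed `Vs` in um/s. Must be >= 0.
#' @param rot_diffusion Rotational diffusion coefficient `Dr` in 1/s (or the
#'   tumble rate for run-and-tumble swimmers). Must be > 0.
#' @param bretherton Bretherton shape parameter `beta` in `[0, 1)`: 0 for a
#'   sphere, approaching 1 for an infinitely elongated spheroid.
#' @param thermal_diffusivity Translational thermal diffusivity `DT` in um^2/s,
#'   added to the activity-driven effective diffusivity. Default 0.
#' @param name Optional label used in printing and output files.
#'
#' @return An object of class `bacterium_params`.
#' @seealso [species_presets()], [dimensionless_groups()],
#'   [quiescent_diffusivity()]
#' @export
#' @examples
#' bacterium_params(swim_speed = 22, rot_diffusion = 1, bretherton = 0.88)
bacterium_params <- function(swim_speed, rot_diffusion, bretherton,
                             thermal_diffusivity = 0, name = NULL) {
  stop_if_not_scalar(swim_speed, "swim_speed")
  stop_if_not_scalar(rot_diffusion, "rot_diffusion")
  stop_if_not_scalar(bretherton, "bretherton")
  stop_if_not_scalar(thermal_diffusivity, "thermal_diffusivity")
  if (swim_speed < 0) {
    stop("invalid parameter: swim_speed must be >= 0", call. = FALSE)
  }
  if (rot_diffusion <= 0) {
    stop("invalid parameter: rot_diffusion must be > 0", call. = FALSE)
  }
  if (bretherton < 0 || bretherton >= 1) {
    stop("invalid parameter: bretherton must lie in [0, 1)", call. = FALSE)
  }
  if (thermal_diffusivity < 0) {
    stop("invalid parameter: thermal_diffusivity must be >= 0", call. = FALSE)
  }
  structure(
    list(
      swim_speed = as.numeric(swim_speed),
      rot_diffusion = as.numeric(rot_diffusion),
      bretherton = as.numeric(bretherton),
      thermal_diffusivity = as.numeric(thermal_diffusivity),
      name = name
    ),
    class = "bacterium_params"
  )
}

#' @export
print.bacterium_params <- function(x, ...) {
  cat("Bacterium parameters", if (!is.null(x$name)) paste0("(", x$name, ")"),
      "\n")
  cat(sprintf("  swim speed Vs       : %g um/s\n", x$swim_speed))
  cat(sprintf("  rot. diffusion Dr   : %g 1/s\n", x$rot_diffusion))
  cat(sprintf("  Bretherton beta     : %g\n", x$bretherton))
  cat(sprintf("  thermal diff. DT    : %g um^2/s\n", x$thermal_diffusivity))
  invisible(x)
}

#' Flow parameters
#'
#' Shear rate and flow lengthscale describing a linear shear flow
#' `u = shear_rate * y` in the x-direction. The reference velocity scale
#' `U = shear_rate * lengthscale` is derived, never stored.
#'
#' @param shear_rate Wall shear rate in 1/s. Must be > 0.
#' @param lengthscale Flow lengthscale `L` in um (e.g. pipe radius or viscous
#'   boundary-layer height). Must be > 0.
#' @param name Optional scenario label.
#'
#' @return An object of class `flow_params`.
#' @export
#' @examples
#' flow_params(shear_rate = 1, lengthscale = 750)
flow_params <- function(shear_rate, lengthscale, name = NULL) {
  stop_if_not_scalar(shear_rate, "shear_rate")
  stop_if_not_scalar(lengthscale, "lengthscale")
  if (shear_rate <= 0) {
    stop("invalid parameter: shear_rate must be > 0", call. = FALSE)
  }
  if (lengthscale <= 0) {
    stop("invalid parameter: lengthscale must be > 0", call. = FALSE)
  }
  structure(
    list(shear_rate = as.numeric(shear_rate),
         lengthscale = as.numeric(lengthscale), name = name),
    class = "flow_params"
  )
}

#' @export
print.flow_params <- function(x, ...) {
  cat("Flow parameters", if (!is.null(x$name)) paste0("(", x$name, ")"), "\n")
  cat(sprintf("  shear rate  : %g 1/s\n", x$shear_rate))
  cat(sprintf("  lengthscale : %g um\n", x$lengthscale))
  cat(sprintf("  velocity U  : %g um/s (derived)\n",
              x$shear_rate * x$lengthscale))
  invisible(x)
}

#' Dimensionless groups of the adhesion problem
#'
#' The relative swimming speed `vs = Vs / (shear_rate * L)` (ratio of the
#' swimming speed to the flow speed) and the rotational Peclet number
#' `per = shear_rate / Dr` (ratio of fluid rotation to rotational diffusion).
#'
#' @param bacterium A [bacterium_params()] object, or a numeric `vs` when
#'   constructing the groups directly (then `flow` is interpreted as `per`).
#' @param flow A [flow_params()] object (or numeric `per`, see above).
#'
#' @return An object of class `dimensionless_groups` with fields
#'   `rel_swim_speed` (vs) and `rot_peclet` (per).
#' @export
#' @examples
#' b <- species_presets("ecoli")
#' f <- flow_params(1, 750)
#' dimensionless_groups(b, f)
dimensionless_groups <- function(bacterium, flow) {
  if (is.numeric(bacterium) && is.numeric(flow)) {
    vs <- bacterium
    per <- flow
  } else {
    stopifnot(inherits(bacterium, "bacterium_params"),
              inherits(flow, "flow_params"))
    vs <- bacterium$swim_speed / (flow$shear_rate * flow$lengthscale)
    per <- flow$shear_rate / bacterium$rot_diffusion
  }
  if (vs < 0) stop("invalid parameter: rel_swim_speed must be >= 0",
                   call. = FALSE)
  if (per <= 0) stop("invalid parameter: rot_peclet must be > 0",
                     call. = FALSE)
  structure(list(rel_swim_speed = vs, rot_peclet = per),
            class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf("Dimensionless groups: vs = %g, Per = %g\n",
              x$rel_swim_speed, x$rot_peclet))
  invisible(x)
}

#' Quiescent effective diffusivity of a swimmer
#'
#' In a quiescent fluid, run-and-reorient swimming produces an isotropic
#' effective diffusivity `Vs^2 / (2 Dr)` in two dimensions. This is the
#' zero-shear limit of [effective_diffusivity()] (before adding `DT`).
#'
#' @param bacterium A [bacterium_params()] object.
#' @return Diffusivity in um^2/s.
#' @export
#' @examples
#' quiescent_diffusivity(species_presets("ecoli"))  # ~240 um^2/s
quiescent_diffusivity <- function(bacterium) {
  stopifnot(inherits(bacterium, "bacterium_params"))
  bacterium$swim_speed^2 / (2 * bacterium$rot_diffusion)
}

#' Built-in species parameter sets
#'
#' Motility parameters for the two reference species used throughout the
#' package. E. coli (strains HCB437/RP437): Vs = 22 um/s, Dr = 1 1/s (tumble
#' rate), beta = 0.88. P. aeruginosa (PAO1): Vs = 23 um/s, Dr = 0.036 1/s,
#' beta = 0.88. Point estimates are used; measurement uncertainties are not
#' propagated. Thermal diffusivity is 0 in both fixtures: for these species
#' it is three orders of magnitude below the activity-driven diffusivity
#' (about 0.2 vs 240 um^2/s for E. coli), which is what justifies neglecting
#' Brownian motion; pass `thermal_diffusivity` to [bacterium_params()] to
#' include it.
#'
#' @param species One of `"ecoli"`, `"paeruginosa"`, or `NULL` to list all.
#' @return A [bacterium_params()] object, or a named list of them.
#' @export
#' @examples
#' species_presets("paeruginosa")
#' names(species_presets())
species_presets <- function(species = NULL) {
  presets <- list(
    ecoli = bacterium_params(22, 1, 0.88, name = "E. coli"),
    paeruginosa = bacterium_params(23, 0.036, 0.88, name = "P. aeruginosa")
  )
  if (is.null(species)) return(presets)
  key <- match.arg(species, names(presets))
  presets[[key]]
}

#' Built-in flow scenario presets
#'
#' Wall shear rate ranges and flow lengthscales for industrial and medical
#' systems prone to biofilm formation. Each entry records the lower and upper
#' wall shear rates (1/s) and the lengthscale (um).
#'
#' @param scenario One of `"small_catheter"`, `"large_catheter"`,
#'   `"intestine"`, `"river"`, `"artery"`, or `NULL` to list all.
#' @return A list with fields `shear_lo`, `shear_hi`, `lengthscale`, `name`
#'   (or a named list of such entries).
#' @export
#' @examples
#' scenario_presets("river")
scenario_presets <- function(scenario = NULL) {
  presets <- list(
    small_catheter = list(shear_lo = 0.12, shear_hi = 5.09,
                          lengthscale = 1000, name = "Small catheter"),
    large_catheter = list(shear_lo = 0.038, shear_hi = 1.51,
                          lengthscale = 1500, name = "Large catheter"),
    intestine = list(shear_lo = 0.2, shear_hi = 80,
                     lengthscale = 12500, name = "Human small intestine"),
    river = list(shear_lo = 5.9, shear_hi = 21.7,
                 lengthscale = 10000, name = "Slowly flowing river"),
    artery = list(shear_lo = 100, shear_hi = 350,
                  lengthscale = 2600, name = "Human coronary artery")
  )
  if (is.null(scenario)) return(presets)
  key <- match.arg(scenario, names(presets))
  presets[[key]]
}

#' Load parameters from a YAML config file
#'
#' Reads a structured key-value file with optional `bacterium` and `flow`
#' sections, each mirroring the constructor arguments. A `species` string in
#' the `bacterium` section resolves a built-in preset instead.
#'
#' @param path Path to a YAML file.
#' @return A list with components `bacterium` and/or `flow` (others passed
#'   through untouched).
#' @export
load_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- cfg
  if (!is.null(cfg$bacterium)) {
    b <- cfg$bacterium
    out$bacterium <- if (!is.null(b$species)) {
      species_presets(b$species)
    } else {
      bacterium_params(b$swim_speed, b$rot_diffusion, b$bretherton,
                       thermal_diffusivity = b$thermal_diffusivity %||% 0,
                       name = b$name)
    }
  }
  if (!is.null(cfg$flow)) {
    f <- cfg$flow
    out$flow <- flow_params(f$shear_rate, f$lengthscale, name = f$name)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("invalid parameter: %s must be a finite numeric scalar", nm),
         call. = FALSE)
  }
  invisible(TRUE)
}
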