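#' Effective Peclet number of the adhesion boundary layer
#'
#' Shear- and shape-dependent Peclet number governing wall-normal dispersion
#' in the depleted near-wall layer:
#' \deqn{Pe_{\rm eff} = \frac{(16+\mathrm{Per}^2)\,(16+(4-\beta^2)\mathrm{Per}^2)}
#'   {4\,\mathrm{Per}\,v_s^2\,(32+(2-\beta)(1-\beta)\mathrm{Per}^2)}.}
#' For spheres this reduces to \eqn{(4+\mathrm{Per}^2)/(2\,\mathrm{Per}\,v_s^2)},
#' and as \eqn{\mathrm{Per} \to 0} it approaches the quiescent Peclet number
#' \eqn{2/(v_s^2 \mathrm{Per}) = UL/D_{\rm quies}}.
#'
#' @param groups A [dimensionless_groups()] object.
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @param check_validity Warn outside the closure accuracy envelope
#'   ([closure_validity()]).
#' @return Dimensionless effective Peclet number.
#' @export
#' @examples
#' effective_peclet(dimensionless_groups(0.01, 1), beta = 0)  # 25000
effective_peclet <- function(groups, beta, check_validity = FALSE) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  vs <- groups$rel_swim_speed
  per <- groups$rot_peclet
  if (beta < 0 || beta >= 1) {
    stop("invalid parameter: beta must lie in [0, 1)", call. = FALSE)
  }
  if (vs == 0 || per == 0) {
    stop(paste("effective Peclet number diverges in the quiescent limit",
               "(rel_swim_speed and rot_peclet must both be positive)"),
         call. = FALSE)
  }
  if (check_validity) closure_validity(beta, per)
  (16 + per^2) * (16 + (4 - beta^2) * per^2) /
    (4 * per * vs^2 * (32 + (2 - beta) * (1 - beta) * per^2))
}

#' Quiescent Peclet number
#'
#' `UL / Dquies = 2 / (vs^2 Per)`: the Peclet number when dispersion is set by
#' motility alone, ignoring shear-induced reorientation. The low-shear limit
#' of [effective_peclet()].
#'
#' @inheritParams effective_peclet
#' @return Dimensionless Peclet number.
#' @export
quiescent_peclet <- function(groups) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  2 / (groups$rel_swim_speed^2 * groups$rot_peclet)
}

#' Effective diffusivity in the adhesion boundary layer
#'
#' Dimensional form of the shear-dependent dispersion coefficient:
#' \deqn{D_{\rm eff} = \frac{4 D_r V_s^2\,(32 D_r^2 + (2-\beta)(1-\beta)\dot\gamma^2)}
#'   {(16 D_r^2 + (4-\beta^2)\dot\gamma^2)(16 D_r^2 + \dot\gamma^2)} + D_T,}
#' where the thermal diffusivity `DT` of the swimmer is simply added. As the
#' shear rate vanishes this tends to the quiescent diffusivity
#' `Vs^2/(2 Dr) + DT`; at high shear it decays as `1/shear_rate^2`, which is
#' what caps the adhesion rate at a critical shear rate.
#'
#' @param bacterium A [bacterium_params()] object.
#' @param shear_rate Shear rate in 1/s, > 0 (vectorised).
#' @return Diffusivity in um^2/s.
#' @export
#' @examples
#' effective_diffusivity(species_presets("ecoli"), shear_rate = 1)
effective_diffusivity <- function(bacterium, shear_rate) {
  stopifnot(inherits(bacterium, "bacterium_params"))
  if (any(shear_rate <= 0)) {
    stop("invalid parameter: shear_rate must be > 0", call. = FALSE)
  }
  vs <- bacterium$swim_speed
  dr <- bacterium$rot_diffusion
  b <- bacterium$bretherton
  g2 <- shear_rate^2
  4 * dr * vs^2 * (32 * dr^2 + (2 - b) * (1 - b) * g2) /
    ((16 * dr^2 + (4 - b^2) * g2) * (16 * dr^2 + g2)) +
    bacterium$thermal_diffusivity
}

#' Mean orientation in the boundary layer
#'
#' Leading-order polar order generated inside the depletion layer by the
#' balance of shear alignment, rotational diffusion, and swimming down the
#' vertical density gradient. Both components are linear in the gradient:
#' \deqn{\rho n_y = -\frac{4\,\mathrm{Per}\,v_s\,(32+(2-\beta)(1-\beta)\mathrm{Per}^2)}
#'   {\varepsilon\,(16+\mathrm{Per}^2)(16+(4-\beta^2)\mathrm{Per}^2)}\,
#'   \partial_{\tilde y}\rho,}
#' \deqn{\rho n_x = -\frac{\mathrm{Per}^2\,v_s\,(64+46\beta+(4-\beta^2)\mathrm{Per}^2)}
#'   {\varepsilon\,(16+\mathrm{Per}^2)(16+(4-\beta^2)\mathrm{Per}^2)}\,
#'   \partial_{\tilde y}\rho.}
#' A density increasing away from the wall (negative gradient convention here:
#' `density_gradient` is `d rho / d ytilde`) yields net swimming toward the
#' wall. The vertical coefficient is tied to [effective_peclet()] by the exact
#' identity `vs * |coef_y| / eps^2 = 1 / (eps^3 Peeff)`.
#'
#' @param density_gradient Vertical density gradient `d rho / d ytilde` in
#'   boundary-layer coordinates.
#' @param groups A [dimensionless_groups()] object.
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @param epsilon Boundary-layer thickness scale, > 0.
#' @return Named numeric vector `c(rho_nx, rho_ny)`.
#' @export
boundary_layer_orientation <- function(density_gradient, groups, beta,
                                       epsilon) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  vs <- groups$rel_swim_speed
  per <- groups$rot_peclet
  denom <- epsilon * (16 + per^2) * (16 + (4 - beta^2) * per^2)
  coef_y <- -4 * per * vs * (32 + (2 - beta) * (1 - beta) * per^2) / denom
  coef_x <- -per^2 * vs * (64 + 46 * beta + (4 - beta^2) * per^2) / denom
  c(rho_nx = coef_x * density_gradient, rho_ny = coef_y * density_gradient)
}

#' Similarity solution for the near-wall density
#'
#' Uniformly valid density field of the active Leveque problem with a
#' perfectly absorbing wall:
#' \deqn{\rho(x, y) = \frac{\gamma\!\left(\tfrac13,\;
#'   \frac{Pe_{\rm eff}\, y^3}{9x}\right)}{\Gamma(1/3)},}
#' with \eqn{\gamma} the lower incomplete gamma function (evaluated in
#' regularised form via `pgamma` for numerical stability). Zero at the wall,
#' tending to the far-field value 1, monotone increasing in `y`.
#'
#' @param x Downstream position(s), > 0 (dimensionless).
#' @param y Wall-normal position(s), >= 0 (dimensionless).
#' @param peeff Effective Peclet number.
#' @return Dimensionless density in `[0, 1]` (recycled over `x`, `y`).
#' @export
#' @examples
#' density_field(1, c(0, 0.05, 1), peeff = 25000)
density_field <- function(x, y, peeff) {
  if (any(x <= 0)) stop("domain error: x must be > 0", call. = FALSE)
  if (any(y < 0)) stop("domain error: y must be >= 0", call. = FALSE)
  stats::pgamma(peeff * y^3 / (9 * x), shape = 1 / 3)
}

#' Local adhesion rate (dimensionless)
#'
#' Wall flux of the similarity solution at downstream position `x`:
#' \deqn{J(x) = \frac{3^{1/3}}{\Gamma(1/3)\,Pe_{\rm eff}^{2/3}\,x^{1/3}},}
#' with leading coefficient `3^(1/3)/gamma(1/3) = 0.538...`, decaying as
#' `x^(-1/3)` downstream.
#'
#' @param x Downstream position(s), > 0.
#' @param peeff Effective Peclet number.
#' @return Dimensionless adhesion rate per unit surface length.
#' @export
#' @examples
#' adhesion_rate(1, peeff = 1)  # the Leveque prefactor 0.5384
adhesion_rate <- function(x, peeff) {
  if (any(x <= 0)) stop("domain error: x must be > 0", call. = FALSE)
  3^(1 / 3) / (gamma(1 / 3) * peeff^(2 / 3) * x^(1 / 3))
}

#' Local adhesion rate (dimensional)
#'
#' \deqn{\hat J(\hat x) = \frac{3^{1/3} \rho_\infty D_{\rm eff}^{2/3}
#'   \dot\gamma^{1/3}}{\Gamma(1/3)\, \hat x^{1/3}},}
#' in cells per um of surface per second, linear in the inlet density
#' `rho_inf` (cells/um^2). Nondimensionalising with shear rate and
#' lengthscale recovers [adhesion_rate()] exactly.
#'
#' @param x_dim Downstream position in um, > 0.
#' @param bacterium A [bacterium_params()] object.
#' @param shear_rate Shear rate in 1/s (vectorised).
#' @param inlet_density Inlet bacterial density `rho_inf` in cells/um^2.
#' @return Adhesion rate in cells um^-1 s^-1.
#' @export
dimensional_adhesion_rate <- function(x_dim, bacterium, shear_rate,
                                      inlet_density = 1) {
  if (any(x_dim <= 0)) stop("domain error: x_dim must be > 0", call. = FALSE)
  deff <- effective_diffusivity(bacterium, shear_rate)
  3^(1 / 3) * inlet_density * deff^(2 / 3) * shear_rate^(1 / 3) /
    (gamma(1 / 3) * x_dim^(1 / 3))
}

#' Critical shear rate of maximal adhesion
#'
#' The adhesion rate grows like `shear_rate^(1/3)` at low shear (enhanced
#' mass transport) but decays like `1/shear_rate` at high shear
#' (shear-induced reorientation starves the wall), so it has a unique
#' interior maximum. This function maximises
#' `(Deff + DT)^(2/3) * shear_rate^(1/3)` over log shear rate by bracketed
#' golden-section/parabolic search on `[1e-3 Dr, 1e3 Dr]`.
#'
#' For spheres with `DT = 0` the maximiser is `2 Dr / sqrt(3)` in closed
#' form; for the built-in E. coli and P. aeruginosa parameters it is 1.1 and
#' 0.039 1/s to two significant figures.
#'
#' @param bacterium A [bacterium_params()] object.
#' @param tol Relative tolerance of the maximiser.
#' @return Critical shear rate in 1/s.
#' @export
#' @examples
#' signif(critical_shear(species_presets("ecoli")), 2)  # 1.1
critical_shear <- function(bacterium, tol = 1e-10) {
  stopifnot(inherits(bacterium, "bacterium_params"), tol > 0)
  dr <- bacterium$rot_diffusion
  obj <- function(lg) {
    g <- exp(lg)
    (2 / 3) * log(effective_diffusivity(bacterium, g)) + lg / 3
  }
  lo <- log(1e-3 * dr)
  hi <- log(1e3 * dr)
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = tol)
  edge <- 10 * tol * (hi - lo)
  if (opt$maximum - lo < edge || hi - opt$maximum < edge) {
    stop("critical shear rate could not be bracketed in [1e-3 Dr, 1e3 Dr]",
         call. = FALSE)
  }
  exp(opt$maximum)
}

#' Net adhesion to a surface of finite length (dimensionless)
#'
#' Integral of [adhesion_rate()] over `x` in `(0, surface_length]`, in closed
#' form:
#' \deqn{\int_0^l J\,dx = \frac{3}{2}\cdot\frac{3^{1/3}}{\Gamma(1/3)}\,
#'   l^{2/3}\, Pe_{\rm eff}^{-2/3}.}
#'
#' @param surface_length Dimensionless surface length `l`, > 0.
#' @param peeff Effective Peclet number.
#' @return Dimensionless net adhesion rate.
#' @export
net_adhesion <- function(surface_length, peeff) {
  if (any(surface_length <= 0)) {
    stop("domain error: surface_length must be > 0", call. = FALSE)
  }
  1.5 * 3^(1 / 3) / gamma(1 / 3) * surface_length^(2 / 3) * peeff^(-2 / 3)
}

#' Scaling factor for the net-adhesion collapse
#'
#' \deqn{S(\beta, \mathrm{Per}, v_s) =
#'   \frac{(16+(4-\beta^2)\mathrm{Per}^2)^{2/3}}
#'   {v_s^{4/3}\,(32+(2-\beta)(1-\beta)\mathrm{Per}^2)^{2/3}}.}
#' Multiplying the net adhesion rate by `S` removes its dependence on shape
#' and swimming speed: the scaled theory curve depends on `Per` and the
#' surface length alone, which is what collapses simulations of different
#' species onto a single curve.
#'
#' @param beta Bretherton shape parameter.
#' @param groups A [dimensionless_groups()] object.
#' @return Dimensionless scaling factor.
#' @export
scaling_S <- function(beta, groups) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  vs <- groups$rel_swim_speed
  per <- groups$rot_peclet
  (16 + (4 - beta^2) * per^2)^(2 / 3) /
    (vs^(4 / 3) * (32 + (2 - beta) * (1 - beta) * per^2)^(2 / 3))
}

#' Scaled net adhesion
#'
#' Applies the collapse scaling to a measured or predicted net adhesion rate:
#' `Jbar = S(beta, Per, vs) * net_rate / inlet_density`. Applied to the
#' closed-form [net_adhesion()] this reduces to
#' \deqn{\bar J = \frac{3}{2}\cdot\frac{3^{1/3}}{\Gamma(1/3)}\, l^{2/3}
#'   \left(\frac{4\,\mathrm{Per}}{16+\mathrm{Per}^2}\right)^{2/3},}
#' independent of `beta` and `vs`, maximal at `Per = 4`.
#'
#' @param net_rate Net adhesion rate (events per unit time for simulation
#'   data, or the dimensionless [net_adhesion()] for theory with
#'   `inlet_density = 1`).
#' @param beta Bretherton shape parameter.
#' @param groups A [dimensionless_groups()] object.
#' @param inlet_density Density conversion constant (cells per unit area for
#'   simulation event rates; 1 for theory curves).
#' @return Scaled net adhesion `Jbar`.
#' @export
scaled_net_adhesion <- function(net_rate, beta, groups, inlet_density = 1) {
  scaling_S(beta, groups) * net_rate / inlet_density
}

#' Theoretical collapse curve of scaled net adhesion
#'
#' The closed-form scaled net adhesion as a function of the rotational Peclet
#' number and surface length alone (see [scaled_net_adhesion()]).
#'
#' @param rot_peclet Rotational Peclet number(s).
#' @param surface_length Dimensionless surface length `l`.
#' @return Scaled net adhesion `Jbar` (same shape as `rot_peclet`).
#' @export
#' @examples
#' collapse_curve(1, surface_length = 3)  # 0.6402...
collapse_curve <- function(rot_peclet, surface_length) {
  1.5 * 3^(1 / 3) / gamma(1 / 3) * surface_length^(2 / 3) *
    (4 * rot_peclet / (16 + rot_peclet^2))^(2 / 3)
}

#' Theory curve of local adhesion rate along a surface
#'
#' Tabulates the local adhesion rate on a grid of downstream positions plus
#' its closed-form integral over the surface, either nondimensionally or, if
#' a bacterium/flow pair is supplied, dimensionally.
#'
#' @param positions Strictly positive, increasing downstream positions
#'   (dimensionless, or um if dimensional).
#' @param groups A [dimensionless_groups()] object.
#' @param beta Bretherton shape parameter.
#' @param bacterium,flow Optional [bacterium_params()] and [flow_params()];
#'   when both are given the curve is dimensional (cells um^-1 s^-1) with
#'   `inlet_density`.
#' @param inlet_density Inlet density for the dimensional form.
#' @return An object of class `theory_curve`: data frame `positions`,
#'   `local_rate` plus attributes `net_rate`, `dimensional`, `params`.
#' @export
theory_curve <- function(positions, groups, beta, bacterium = NULL,
                         flow = NULL, inlet_density = 1) {
  stopifnot(all(diff(positions) > 0), all(positions > 0))
  dimensional <- !is.null(bacterium) && !is.null(flow)
  if (dimensional) {
    rate <- dimensional_adhesion_rate(positions, bacterium, flow$shear_rate,
                                      inlet_density)
    l <- max(positions)
    net <- 1.5 * rate[length(rate)] * l  # (3/2) J(l) l = closed-form integral
  } else {
    peeff <- effective_peclet(groups, beta)
    rate <- adhesion_rate(positions, peeff)
    net <- net_adhesion(max(positions), peeff)
  }
  structure(
    data.frame(positions = positions, local_rate = rate),
    net_rate = net, dimensional = dimensional,
    params = list(groups = groups, beta = beta),
    class = c("theory_curve", "data.frame")
  )
}

#' Export a theory curve as CSV
#'
#' Writes positions and local rates with a commented header recording the
#' generating parameters, the net rate, and the units flag.
#'
#' @param curve A [theory_curve()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_theory_curve <- function(curve, path) {
  stopifnot(inherits(curve, "theory_curve"))
  p <- attr(curve, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vs = %.17g, per = %.17g, beta = %.17g",
                     p$groups$rel_swim_speed, p$groups$rot_peclet, p$beta),
             con)
  writeLines(sprintf("# net_rate = %.17g", attr(curve, "net_rate")), con)
  writeLines(sprintf("# dimensional = %s", attr(curve, "dimensional")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' Classify the validity regime of the boundary-layer theory
#'
#' The closed-form adhesion law rests on asymptotic assumptions that fail in
#' four labelled regions of parameter space, checked in fixed precedence
#' order A, B, C, D. The reference small scale is the dimensionless bacterium
#' body length `eps_body` (default 5e-4: a 5 um body in a 1 cm flow), and the
#' depletion-layer thickness scale is `Peeff^(-1/3)` (the layer thickness at
#' unit downstream position; the downstream station is a documented choice).
#' * `A` - `vs >= 1`: swimming competes with the flow far from the wall,
#'   altering the outer transport balance.
#' * `B` - `Peeff^(-1/3) <= eps_body`: the depletion layer is thinner than a
#'   cell body, so cells traverse it ballistically.
#' * `C` - `Per >= 1/eps_body`: shear-dominated reorientation leaves too few
#'   cells facing the wall for the orientation law to hold.
#' * `D` - `vs <= eps_body`: swimming so slow relative to the flow that the
#'   near-wall orientation response is not the leading transport mechanism.
#' Otherwise `VALID`. In B and C the closed-form rate still provides an
#' upper bound on adhesion.
#'
#' @param groups A [dimensionless_groups()] object.
#' @param beta Bretherton shape parameter.
#' @param eps_threshold Dimensionless body length `eps_body`.
#' @return An object of class `regime_label`: list with `label` and the
#'   `thresholds` record `(vs, per, thickness, eps_body)` used.
#' @export
#' @examples
#' classify_regime(dimensionless_groups(0.03, 1), beta = 0.88)$label
classify_regime <- function(groups, beta, eps_threshold = 5e-4) {
  stopifnot(inherits(groups, "dimensionless_groups"), eps_threshold > 0)
  vs <- groups$rel_swim_speed
  per <- groups$rot_peclet
  thickness <- if (vs > 0) effective_peclet(groups, beta)^(-1 / 3) else 0
  label <- if (vs >= 1) "A"
  else if (thickness <= eps_threshold) "B"
  else if (per >= 1 / eps_threshold) "C"
  else if (vs <= eps_threshold) "D"
  else "VALID"
  structure(list(label = label,
                 thresholds = c(vs = vs, per = per, thickness = thickness,
                                eps_body = eps_threshold)),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime %s (vs = %.3g, Per = %.3g, layer thickness = %.3g)\n",
              x$label, x$thresholds["vs"], x$thresholds["per"],
              x$thresholds["thickness"]))
  invisible(x)
}
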