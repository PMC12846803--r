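#' Flow tensors of unit shear
#'
#' Rate-of-strain `E` and rate-of-rotation `W` tensors of the unit shear flow
#' `u = y * xhat`, in shear-rate units: both have off-diagonal entries of
#' magnitude 1/2.
#'
#' @return A list with symmetric `strain` and antisymmetric `rotation`
#'   2x2 matrices.
#' @export
flow_tensors <- function() {
  list(
    strain = matrix(c(0, 0.5, 0.5, 0), 2, 2),
    rotation = matrix(c(0, -0.5, 0.5, 0), 2, 2)
  )
}

#' Jeffery angular drift in unit shear
#'
#' Deterministic rotation rate of a spheroid with orientation angle `theta`
#' (measured counterclockwise from the flow axis) in unit shear flow. It is
#' the tangential projection of `(beta*E + W) s` for `s = (cos theta,
#' sin theta)`:
#' \deqn{\omega(\theta) = \tfrac12(\beta \cos 2\theta - 1).}
#' The drift is always clockwise (\eqn{\omega \le 0}), strictly so for
#' `beta < 1`: elongated bodies slow down near flow alignment (`theta = 0,
#' pi`) but never stop.
#'
#' @param theta Orientation angle(s) in radians.
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @return Angular velocity per unit shear rate (same shape as `theta`).
#' @export
#' @examples
#' jeffery_drift(0, 0)        # -1/2 : sphere rotates at half the vorticity
#' jeffery_drift(0, 0.88)     # -0.06: slow near flow alignment
jeffery_drift <- function(theta, beta) {
  if (beta < 0 || beta >= 1) {
    stop("invalid parameter: beta must lie in [0, 1)", call. = FALSE)
  }
  0.5 * (beta * cos(2 * theta) - 1)
}

#' Steady orientation distribution in shear (diffusive Jeffery orbits)
#'
#' Solves the stationary orientation Fokker-Planck balance on the circle, in
#' shear-rate units,
#' \deqn{\partial_\theta[\omega(\theta) p] =
#'   \mathrm{Per}^{-1} \partial^2_\theta p,}
#' with \eqn{\omega} the Jeffery drift, by Fourier spectral collocation on a
#' uniform periodic grid. The constant probability flux around the circle is
#' retained (the drift has nonzero mean), so the solution is the distribution
#' of diffusive Jeffery orbits: uniform for spheres, peaked at flow alignment
#' (`theta = 0, pi`) for elongated swimmers.
#'
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @param rot_peclet Rotational Peclet number `Per > 0`.
#' @param resolution Number of (even) collocation nodes, at least 64.
#' @param residual_tol Maximum allowed max-norm residual of the discrete
#'   stationary balance.
#' @return An object of class `orientation_pdf`: list with `grid` (angles on
#'   `[0, 2pi)`), `density` (1/radian, integrating to 1), `beta`,
#'   `rot_peclet`, `resolution`, `residual`.
#' @export
#' @examples
#' p <- steady_orientation_pdf(0.88, 1)
#' p$grid[which.max(p$density)]  # near 0 or pi: flow-aligned
steady_orientation_pdf <- function(beta, rot_peclet, resolution = 512,
                                   residual_tol = 1e-8) {
  if (rot_peclet <= 0) {
    stop("invalid parameter: rot_peclet must be > 0", call. = FALSE)
  }
  n <- as.integer(resolution)
  if (n < 64) stop("resolution must be at least 64", call. = FALSE)
  if (n %% 2L != 0L) n <- n + 1L
  h <- 2 * pi / n
  theta <- h * (0:(n - 1))

  # Periodic spectral differentiation matrices (even number of nodes)
  k <- outer(0:(n - 1), 0:(n - 1), "-")
  sgn <- (-1)^k
  half <- k * h / 2
  d1 <- ifelse(k == 0, 0, 0.5 * sgn / tan(half))
  d2 <- ifelse(k == 0, -pi^2 / (3 * h^2) - 1 / 6,
               -sgn / (2 * sin(half)^2))

  omega <- jeffery_drift(theta, beta)
  a <- d1 %*% diag(omega) - d2 / rot_peclet

  # Stationary nullspace with unit-mass constraint appended (uniform weights
  # are the spectrally accurate periodic quadrature)
  rhs <- c(rep(0, n), 1)
  p <- qr.solve(rbind(a, rep(h, n)), rhs)

  res <- max(abs(a %*% p))
  if (!is.finite(res) || res > residual_tol) {
    stop(sprintf(
      "orientation Fokker-Planck solve did not converge: residual %.3e > %.3e at resolution %d",
      res, residual_tol, n), call. = FALSE)
  }
  p <- p / (h * sum(p))

  structure(
    list(grid = theta, density = as.numeric(p), beta = beta,
         rot_peclet = rot_peclet, resolution = n, residual = res),
    class = "orientation_pdf"
  )
}

#' @export
print.orientation_pdf <- function(x, ...) {
  cat(sprintf(
    "Steady orientation distribution: beta = %g, Per = %g, %d nodes (residual %.2e)\n",
    x$beta, x$rot_peclet, x$resolution, x$residual))
  invisible(x)
}

#' Moments of an orientation distribution
#'
#' Polar moment (mean of `s = (cos theta, sin theta)`) and nematic moment
#' (mean of `s s^T - I/2`) by trapezoidal quadrature on the periodic grid.
#' For the steady shear distribution the polar moment vanishes: swimmers
#' align with the flow axis but face up- and downstream equally.
#'
#' @param pdf An [steady_orientation_pdf()] object.
#' @return List with `polar` (length-2) and `nematic` (symmetric traceless
#'   2x2).
#' @export
orientation_moments <- function(pdf) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  h <- 2 * pi / pdf$resolution
  th <- pdf$grid
  p <- pdf$density
  polar <- c(h * sum(p * cos(th)), h * sum(p * sin(th)))
  q11 <- h * sum(p * (cos(th)^2 - 0.5))
  q12 <- h * sum(p * cos(th) * sin(th))
  list(polar = polar, nematic = matrix(c(q11, q12, q12, -q11), 2, 2))
}

#' Sample orientations from a steady distribution
#'
#' Inverse-transform sampling on the cumulative trapezoidal integral of the
#' tabulated density; used to draw inlet orientations for the agent-based
#' simulator.
#'
#' @param pdf An [steady_orientation_pdf()] object.
#' @param n Number of samples.
#' @param seed Optional integer seed; when given, sampling runs under a local
#'   RNG state and does not disturb the session RNG.
#' @return Numeric vector of `n` angles in `[0, 2pi)`.
#' @export
sample_orientations <- function(pdf, n, seed = NULL) {
  stopifnot(inherits(pdf, "orientation_pdf"), n >= 1)
  cdf <- orientation_cdf(pdf)
  draw <- function() {
    u <- stats::runif(n)
    stats::approx(cdf$F, cdf$theta, xout = u, rule = 2,
                  ties = "ordered")$y %% (2 * pi)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Cumulative distribution table on [0, 2pi] for inverse-transform sampling.
orientation_cdf <- function(pdf) {
  th <- c(pdf$grid, 2 * pi)
  p <- c(pdf$density, pdf$density[1])
  dF <- diff(th) * (p[-1] + p[-length(p)]) / 2
  F <- c(0, cumsum(dF))
  F <- F / F[length(F)]
  list(theta = th, F = F)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Far-field nematic order tensor
#'
#' Leading-order steady nematic order of a dilute suspension in shear, from
#' the balance of Jeffery rotation against rotational diffusion:
#' \deqn{Q = \frac{\beta \, \mathrm{Per}}{4(16+\mathrm{Per}^2)}
#'   \begin{pmatrix} \mathrm{Per} & 4 \\ 4 & -\mathrm{Per} \end{pmatrix}.}
#' Zero for spheres; the positive first component for `beta > 0` expresses
#' preferential flow alignment.
#'
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @param rot_peclet Rotational Peclet number `Per > 0`.
#' @param check_validity Warn when `(beta, Per)` fall outside the accuracy
#'   envelope of the moment closure (see [closure_validity()]).
#' @return Symmetric traceless 2x2 matrix.
#' @export
#' @examples
#' far_field_Q(0.88, 1)
far_field_Q <- function(beta, rot_peclet, check_validity = TRUE) {
  if (beta < 0 || beta >= 1) {
    stop("invalid parameter: beta must lie in [0, 1)", call. = FALSE)
  }
  if (rot_peclet <= 0) {
    stop("invalid parameter: rot_peclet must be > 0", call. = FALSE)
  }
  if (check_validity) closure_validity(beta, rot_peclet)
  pre <- beta * rot_peclet / (4 * (16 + rot_peclet^2))
  pre * matrix(c(rot_peclet, 4, 4, -rot_peclet), 2, 2)
}

#' Closure accuracy envelope
#'
#' The moment closures used for the third- and fourth-order orientation
#' tensors are accurate for `Per <= 1` when `beta` is in `(0.5, 1)` (highly
#' elongated), `Per <= 10` for `beta` in `(0, 0.5]` (modestly elongated), and
#' `Per <= 100` for spheres. Outside this envelope a warning (never an error)
#' is emitted.
#'
#' @param beta,rot_peclet Shape parameter and rotational Peclet number.
#' @return `TRUE` (inside the envelope) or `FALSE`, invisibly; warns when
#'   outside.
#' @export
closure_validity <- function(beta, rot_peclet) {
  limit <- if (beta > 0.5) 1 else if (beta > 0) 10 else 100
  ok <- rot_peclet <= limit
  if (!ok) {
    warning(sprintf(
      "closure accuracy envelope exceeded: Per = %g > %g for beta = %g",
      rot_peclet, limit, beta), call. = FALSE)
  }
  invisible(ok)
}

#' Order-parameter state of the suspension
#'
#' Bundles local density `rho`, polar order `n` (mean orientation), and
#' nematic order `Q` (alignment), validating the tensor invariants.
#'
#' @param polar Length-2 numeric, `|polar| <= 1`.
#' @param nematic Symmetric traceless 2x2 matrix.
#' @param density Nonnegative scalar density (default 1).
#' @return An object of class `order_tensors`.
#' @export
order_tensors <- function(polar = c(0, 0), nematic = matrix(0, 2, 2),
                          density = 1) {
  polar <- as.numeric(polar)
  stopifnot(length(polar) == 2, is.matrix(nematic), all(dim(nematic) == 2))
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  if (abs(nematic[1, 2] - nematic[2, 1]) > 1e-12) {
    stop("nematic tensor must be symmetric", call. = FALSE)
  }
  if (abs(sum(diag(nematic))) > 1e-12) {
    stop("nematic tensor must be traceless", call. = FALSE)
  }
  if (sqrt(sum(polar^2)) > 1 + 1e-12) {
    stop("|polar| must be <= 1", call. = FALSE)
  }
  structure(list(polar = polar, nematic = nematic, density = density),
            class = "order_tensors")
}

#' Closure tensors for the orientation moment hierarchy
#'
#' Third-moment tensor `T` (rank 3) and fourth-moment tensor `G` (rank 4)
#' expressed in terms of the lower moments:
#' \deqn{T_{ijk} = \tfrac{\rho}{4}(\delta_{ij} n_k + \delta_{ik} n_j +
#'   \delta_{jk} n_i),}
#' \deqn{G_{ijkl} = \tfrac{\rho}{8}(\delta_{ij}\delta_{kl} +
#'   \delta_{ik}\delta_{jl} + \delta_{il}\delta_{jk}) +
#'   \tfrac{\rho}{6}(\delta_{ij} Q_{kl} + \delta_{ik} Q_{jl} +
#'   \delta_{il} Q_{jk} + \delta_{jk} Q_{il} + \delta_{jl} Q_{ik} +
#'   \delta_{kl} Q_{ij}).}
#' Both are fully symmetric under index permutation.
#'
#' @param state An [order_tensors()] object.
#' @return List with `T` (2x2x2 array) and `G` (2x2x2x2 array).
#' @export
closure_tensors <- function(state) {
  stopifnot(inherits(state, "order_tensors"))
  rho <- state$density
  n <- state$polar
  q <- state$nematic
  d <- diag(2)
  Tt <- array(0, c(2, 2, 2))
  G <- array(0, c(2, 2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    Tt[i, j, k] <- rho / 4 *
      (d[i, j] * n[k] + d[i, k] * n[j] + d[j, k] * n[i])
    for (l in 1:2) {
      G[i, j, k, l] <- rho / 8 *
        (d[i, j] * d[k, l] + d[i, k] * d[j, l] + d[i, l] * d[j, k]) +
        rho / 6 *
        (d[i, j] * q[k, l] + d[i, k] * q[j, l] + d[i, l] * q[j, k] +
         d[j, k] * q[i, l] + d[j, l] * q[i, k] + d[k, l] * q[i, j])
    }
  }
  list(T = Tt, G = G)
}

#' Source-term residual of the far-field moment equations
#'
#' Evaluates the right-hand-side source terms of the spatially uniform moment
#' equations for polar order `rho n` and nematic order `rho Q` in unit shear,
#' using the moment closures of [closure_tensors()]. A state is a steady
#' far-field solution exactly when both residuals vanish; the isotropic state
#' of a spherical swimmer is an exact zero, and the far-field nematic tensor
#' of [far_field_Q()] zeroes the residuals at leading order in `beta`.
#'
#' @param state An [order_tensors()] object.
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @param rot_peclet Rotational Peclet number `Per > 0`.
#' @return List with `polar` (length-2 residual of the polar-order equation)
#'   and `nematic` (2x2 residual of the nematic-order equation).
#' @export
moment_source_residual <- function(state, beta, rot_peclet) {
  stopifnot(inherits(state, "order_tensors"))
  ft <- flow_tensors()
  E <- ft$strain
  W <- ft$rotation
  A <- beta * E + W
  rho <- state$density
  n <- state$polar
  q <- state$nematic
  cl <- closure_tensors(state)

  # polar order: (rho I n - T) : (beta E + W) - rho n / Per
  r_n <- numeric(2)
  for (i in 1:2) {
    acc <- 0
    for (k in 1:2) for (l in 1:2) {
      acc <- acc + (rho * diag(2)[i, k] * n[l] - cl$T[i, k, l]) * A[k, l]
    }
    r_n[i] <- acc - rho * n[i] / rot_peclet
  }

  # nematic order: beta(E M2 + M2 E) + (W M2 - M2 W) - 2 beta G:E - 4 rho Q / Per
  m2 <- rho * (q + diag(2) / 2)
  ge <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ge[i, j] <- sum(cl$G[i, j, , ] * E)
  }
  r_q <- beta * (E %*% m2 + m2 %*% E) + (W %*% m2 - m2 %*% W) -
    2 * beta * ge - 4 * rho * q / rot_peclet

  list(polar = r_n, nematic = r_q)
}

#' Write an orientation distribution to a text table
#'
#' Two numeric columns (angle, density) preceded by comment lines recording
#' the shape parameter, rotational Peclet number, and resolution.
#'
#' @param pdf An [steady_orientation_pdf()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_orientation_pdf <- function(pdf, path) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beta = %.17g", pdf$beta), con)
  writeLines(sprintf("# rot_peclet = %.17g", pdf$rot_peclet), con)
  writeLines(sprintf("# resolution = %d", pdf$resolution), con)
  writeLines("# angle density", con)
  utils::write.table(
    data.frame(angle = pdf$grid, density = pdf$density),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
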