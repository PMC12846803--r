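# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the stationary orientation density comes from
# the constant-flux quadrature formula, not the spectral collocation solve,
# and PDE/flux checks use finite differences on the closed forms.

# Closed-form stationary density of the orientation SDE on the circle with
# drift w(t) = (beta cos 2t - 1)/2 and diffusion D = 1/Per:
#   p(t) = N exp(U(t)) * int_t^{t+2pi} exp(-U(s)) ds,  U = Per * int w,
# evaluated by cumulative trapezoid on a fine grid over [0, 4pi].
fp_oracle_density <- function(beta, per, n = 8192) {
  s <- seq(0, 4 * pi, length.out = 2 * n + 1)
  U <- per * (beta * sin(2 * s) / 4 - s / 2)
  g <- exp(-U)
  G <- c(0, cumsum(diff(s) * (g[-1] + g[-length(g)]) / 2))
  theta <- s[1:(n + 1)]                      # [0, 2pi]
  I <- G[(n + 1):(2 * n + 1)] - G[1:(n + 1)] # int_t^{t+2pi}
  p <- exp(per * (beta * sin(2 * theta) / 4 - theta / 2)) * I
  Z <- sum(diff(theta) * (p[-1] + p[-length(p)]) / 2)
  list(theta = theta, density = p / Z)
}

# Linear interpolation of an oracle density onto arbitrary angles.
fp_oracle_at <- function(oracle, theta) {
  stats::approx(oracle$theta, oracle$density, xout = theta %% (2 * pi),
                rule = 2)$y
}

# Trapezoid quadrature of f over [0, 2pi] on n panels.
circle_quad <- function(f, n = 4096) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  y <- f(t)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

# Brute-force maximizer of the dimensional adhesion objective on a log grid,
# independent of stats::optimize.
grid_max_shear <- function(bacterium, n = 200001) {
  g <- exp(seq(log(1e-3 * bacterium$rot_diffusion),
               log(1e3 * bacterium$rot_diffusion), length.out = n))
  obj <- effective_diffusivity(bacterium, g)^(2 / 3) * g^(1 / 3)
  g[which.max(obj)]
}

# Chi-squared goodness-of-fit of angle samples against an orientation pdf,
# with expected bin masses from the pdf's cumulative integral.
chisq_angles_p <- function(samples, pdf, k = 24) {
  edges <- seq(0, 2 * pi, length.out = k + 1)
  th <- c(pdf$grid, 2 * pi)
  dens <- c(pdf$density, pdf$density[1])
  cum <- c(0, cumsum(diff(th) * (dens[-1] + dens[-length(dens)]) / 2))
  Fe <- stats::approx(th, cum / cum[length(cum)], xout = edges)$y
  expected <- length(samples) * diff(Fe)
  observed <- tabulate(findInterval(samples %% (2 * pi), edges,
                                    rightmost.closed = TRUE), nbins = k)
  stat <- sum((observed - expected)^2 / expected)
  stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
}
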