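#' @useDynLib activeLeveque, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration
#'
#' Full protocol configuration for the agent-based simulator, in
#' nondimensional (shear-rate) units. Defaults follow the full measurement
#' protocol for adhesion runs: timestep 1e-2, domain height 1.5 and length 3,
#' 100 swimmers injected per step, run to t = 10300 with the first 300 time
#' units discarded, and windowed rate estimation over windows of length 2500.
#' See [sim_preset()] for reduced desk-scale presets.
#'
#' @param rel_swim_speed Relative swimming speed `vs = Vs/(shear_rate L)`.
#' @param rot_peclet Rotational Peclet number `Per`.
#' @param beta Bretherton shape parameter in `[0, 1)`.
#' @param dt Timestep (dimensionless), > 0.
#' @param domain_height,domain_length Domain size `H`, `l` > 0.
#' @param n_inject Swimmers injected at the inlet per timestep.
#' @param t_end,t_burnin Total simulated time and discarded initial
#'   transient; `t_burnin < t_end`.
#' @param window_length Length of each averaging window; `t_end - t_burnin`
#'   must divide into at least one whole window.
#' @param seed Integer RNG seed for the run.
#' @param top_boundary Policy at `y = H`: `"reflect"` (specular, default) or
#'   `"periodic"`.
#' @param inlet_orientation `"jeffery"` (steady diffusive Jeffery-orbit
#'   distribution at the run's own `beta`, `Per`; default) or `"uniform"`.
#' @param record_density Accumulate a position histogram.
#' @param record_start Time from which histogram snapshots accumulate
#'   (default `t_burnin`).
#' @param record_every Record every k-th step (thins autocorrelated
#'   snapshots at no cost in bias).
#' @param bins Length-2 integer vector: histogram bins in x and y.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation; identical draws, orders of magnitude slower).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rel_swim_speed, rot_peclet, beta,
                       dt = 1e-2, domain_height = 1.5, domain_length = 3,
                       n_inject = 100, t_end = 10300, t_burnin = 300,
                       window_length = 2500, seed = 1,
                       top_boundary = c("reflect", "periodic"),
                       inlet_orientation = c("jeffery", "uniform"),
                       record_density = FALSE, record_start = t_burnin,
                       record_every = 1L, bins = c(30L, 80L),
                       engine = c("cpp", "r")) {
  top_boundary <- match.arg(top_boundary)
  inlet_orientation <- match.arg(inlet_orientation)
  engine <- match.arg(engine)
  if (dt <= 0) stop("config error: dt must be > 0", call. = FALSE)
  if (domain_height <= 0 || domain_length <= 0) {
    stop("config error: domain dimensions must be > 0", call. = FALSE)
  }
  if (rel_swim_speed < 0 || rot_peclet <= 0 || beta < 0 || beta >= 1) {
    stop("config error: invalid dimensionless parameters", call. = FALSE)
  }
  if (t_burnin >= t_end) {
    stop("config error: t_burnin must be < t_end", call. = FALSE)
  }
  n_windows <- (t_end - t_burnin) / window_length
  if (n_windows < 1 - 1e-9 ||
      abs(n_windows - round(n_windows)) > 1e-9) {
    stop(paste("config error: (t_end - t_burnin) must divide into >= 1",
               "whole windows of window_length"), call. = FALSE)
  }
  cfg <- structure(
    list(rel_swim_speed = rel_swim_speed, rot_peclet = rot_peclet,
         beta = beta, dt = dt, domain_height = domain_height,
         domain_length = domain_length, n_inject = as.integer(n_inject),
         t_end = t_end, t_burnin = t_burnin,
         window_length = window_length, n_windows = as.integer(round(n_windows)),
         seed = as.integer(seed), top_boundary = top_boundary,
         inlet_orientation = inlet_orientation,
         record_density = record_density, record_start = record_start,
         record_every = as.integer(record_every),
         bins = as.integer(bins), engine = engine),
    class = "sim_config")

  # the domain must contain the depletion layer comfortably
  if (rel_swim_speed > 0) {
    peeff <- effective_peclet(
      dimensionless_groups(rel_swim_speed, rot_peclet), beta)
    thickness <- (domain_length / peeff)^(1 / 3)
    if (domain_height < 3 * thickness) {
      warning(sprintf(
        "domain_height %.3g is below 3 boundary-layer thicknesses (%.3g) at x = l",
        domain_height, 3 * thickness), call. = FALSE)
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "ABM config: vs = %g, Per = %g, beta = %g | dt = %g, H = %g, l = %g\n",
    x$rel_swim_speed, x$rot_peclet, x$beta, x$dt, x$domain_height,
    x$domain_length))
  cat(sprintf(
    "  inject %d/step, t in [0, %g], burn-in %g, %d window(s) of %g, seed %d\n",
    x$n_inject, x$t_end, x$t_burnin, x$n_windows, x$window_length, x$seed))
  invisible(x)
}

#' Simulation protocol presets
#'
#' `"adhesion"` and `"density"` reproduce the full measurement protocols
#' (about 1e8 and 1e7 swimmers; hours of compute). `"adhesion_reduced"` and
#' `"density_reduced"` are desk-scale versions (about 100x smaller) suitable
#' for minutes-long runs on one CPU; they keep the same domain geometry and
#' timestep and shrink only the injection rate and run length.
#'
#' @param name Preset name.
#' @param rel_swim_speed,rot_peclet,beta Dimensionless run parameters.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()] object.
#' @export
sim_preset <- function(name = c("adhesion_reduced", "density_reduced",
                                "adhesion", "density"),
                       rel_swim_speed, rot_peclet, beta, ...) {
  name <- match.arg(name)
  args <- switch(name,
    adhesion = list(domain_height = 1.5, domain_length = 3, n_inject = 100L,
                    t_end = 10300, t_burnin = 300, window_length = 2500),
    density = list(domain_height = 0.8, domain_length = 3, n_inject = 100L,
                   t_end = 1000, t_burnin = 300, window_length = 700,
                   record_density = TRUE),
    adhesion_reduced = list(domain_height = 1.5, domain_length = 3,
                            n_inject = 4L, t_end = 550, t_burnin = 150,
                            window_length = 100),
    density_reduced = list(domain_height = 0.8, domain_length = 3,
                           n_inject = 10L, t_end = 400, t_burnin = 150,
                           window_length = 250, record_density = TRUE,
                           record_every = 5L))
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, c(list(rel_swim_speed = rel_swim_speed,
                             rot_peclet = rot_peclet, beta = beta), args))
}

#' Flux-weighted inlet heights
#'
#' Inverse-CDF samples from the height distribution of a uniform suspension
#' advected into the domain by shear flow, `p(y) = 2y/H^2` on `[0, H]`
#' (faster streamlines carry proportionally more cells): `y = H sqrt(u)`.
#'
#' @param n Number of samples.
#' @param domain_height Domain height `H`.
#' @return Numeric vector of heights in `[0, H]`.
#' @export
sample_inlet_positions <- function(n, domain_height) {
  stopifnot(n >= 1, domain_height > 0)
  domain_height * sqrt(stats::runif(n))
}

#' One Euler-Maruyama step of the agent dynamics
#'
#' Advances agent states one timestep in shear-rate units:
#' `x += (y + vs cos theta) dt`, `y += vs sin theta dt`,
#' `theta += (1/2)(beta cos 2 theta - 1) dt + sqrt(2 dt / Per) xi` with `xi`
#' standard normal, wrapping `theta` to `[0, 2pi)`. Boundary processing
#' (absorption, outflow, reflection) is the caller's job; this is the bare
#' step, exposed for diagnostics and verification.
#'
#' @param states Data frame with columns `x`, `y`, `theta`.
#' @param config A [sim_config()] object.
#' @param noise Set `FALSE` for the deterministic drift-only step
#'   (diagnostic mode).
#' @return Updated data frame of states.
#' @export
step_agents <- function(states, config, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            all(c("x", "y", "theta") %in% names(states)))
  vs <- config$rel_swim_speed
  dt <- config$dt
  xi <- if (noise) stats::rnorm(nrow(states)) else 0
  new_x <- states$x + (states$y + vs * cos(states$theta)) * dt
  new_y <- states$y + vs * sin(states$theta) * dt
  new_th <- states$theta + jeffery_drift(states$theta, config$beta) * dt +
    sqrt(2 * dt / config$rot_peclet) * xi
  data.frame(x = new_x, y = new_y, theta = new_th %% (2 * pi))
}

#' Run an agent-based adhesion simulation
#'
#' Full protocol: flux-weighted injection at the inlet each timestep, inlet
#' orientations from the steady diffusive Jeffery-orbit distribution at the
#' run's own `(beta, Per)`, Euler-Maruyama stepping, absorbing wall at
#' `y = 0` (events recorded with the linearly interpolated crossing position
#' and time), outflow at `x = l`, configurable top boundary, and windowed
#' adhesion-rate estimation after the burn-in. Exact agent bookkeeping
#' (`injected = adhered + exited + live`) is returned with the results.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `abm_result` with components `summary` (an
#'   `adhesion_summary`, see [net_adhesion_rate()]), `density` (a
#'   `density_field` or `NULL`), `book` (bookkeeping counts), and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_preset("adhesion_reduced", rel_swim_speed = 0.03,
#'                   rot_peclet = 1, beta = 0, t_end = 250, t_burnin = 50,
#'                   window_length = 100, seed = 7)
#' res <- run_simulation(cfg)
#' res$summary$rate_mean
#' }
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$inlet_orientation == "jeffery") {
    pdf <- steady_orientation_pdf(config$beta, config$rot_peclet)
    cdf <- orientation_cdf(pdf)
  } else {
    cdf <- list(theta = c(0, 2 * pi), F = c(0, 1))
  }

  set.seed(config$seed)
  raw <- if (config$engine == "cpp") {
    abm_run_cpp(
      config$rel_swim_speed, config$rot_peclet, config$beta, config$dt,
      config$domain_height, config$domain_length, config$n_inject,
      config$t_end, config$t_burnin, cdf$F, cdf$theta,
      config$inlet_orientation == "uniform",
      if (config$top_boundary == "reflect") 0L else 1L,
      config$record_density, config$record_start, config$record_every,
      config$bins[1], config$bins[2])
  } else {
    abm_run_r(config, cdf)
  }

  events <- data.frame(time = raw$event_time, x = raw$event_x)
  events <- events[order(events$time), , drop = FALSE]
  summary <- net_adhesion_rate(events, config)

  density <- NULL
  if (config$record_density) {
    density <- density_histogram(
      list(counts = raw$counts, n_snapshots = raw$n_snapshots),
      config, bins = config$bins)
  }

  book <- c(injected = raw$injected, adhered = raw$adhered,
            exited = raw$exited, live = raw$live)
  structure(list(summary = summary, density = density, book = book,
                 config = config),
            class = "abm_result")
}

#' @export
print.abm_result <- function(x, ...) {
  cat(sprintf(
    "ABM run: %g injected, %g adhered, %g exited, %g live\n",
    x$book["injected"], x$book["adhered"], x$book["exited"], x$book["live"]))
  cat(sprintf("  net adhesion rate %.4g +/- %.2g (%d windows)\n",
              x$summary$rate_mean, x$summary$rate_sd, x$summary$n_windows))
  invisible(x)
}

# Pure-R reference engine: identical RNG draw order to the compiled engine
# (per step: inlet heights, inlet orientations, then one normal per live
# agent in storage order), so results match abm_run_cpp exactly.
abm_run_r <- function(config, cdf) {
  vs <- config$rel_swim_speed
  dt <- config$dt
  H <- config$domain_height
  l <- config$domain_length
  noise_amp <- sqrt(2 * dt / config$rot_peclet)
  n_steps <- round(config$t_end / dt)

  x <- numeric(0); y <- numeric(0); th <- numeric(0)
  ev_t <- numeric(0); ev_x <- numeric(0)
  injected <- 0; adhered <- 0; exited <- 0
  nx <- config$bins[1]; ny <- config$bins[2]
  counts <- matrix(0, nx, ny)
  n_snapshots <- 0

  for (step in seq_len(n_steps) - 1L) {
    t0 <- step * dt
    yi <- sample_inlet_positions(config$n_inject, H)
    u <- stats::runif(config$n_inject)
    ti <- if (config$inlet_orientation == "uniform") 2 * pi * u else
      stats::approx(cdf$F, cdf$theta, xout = u, rule = 2,
                    ties = "ordered")$y
    x <- c(x, rep(0, config$n_inject)); y <- c(y, yi); th <- c(th, ti)
    injected <- injected + config$n_inject

    xi <- stats::rnorm(length(x))
    xn <- x + (y + vs * cos(th)) * dt
    yn <- y + vs * sin(th) * dt
    tn <- th + jeffery_drift(th, config$beta) * dt + noise_amp * xi

    hit <- yn <= 0
    if (any(hit)) {
      frac <- y[hit] / (y[hit] - yn[hit])
      et <- t0 + frac * dt
      keep_ev <- et >= config$t_burnin
      ev_t <- c(ev_t, et[keep_ev])
      ex <- pmin(pmax(x[hit] + frac * (xn[hit] - x[hit]), 0),
                 config$domain_length)
      ev_x <- c(ev_x, ex[keep_ev])
      adhered <- adhered + sum(hit)
    }
    out <- !hit & xn > l
    exited <- exited + sum(out)
    live <- !hit & !out

    x <- xn[live]; y <- yn[live]; tn <- tn[live]
    top <- y > H
    if (any(top)) {
      if (config$top_boundary == "reflect") {
        y[top] <- 2 * H - y[top]
        tn[top] <- -tn[top]
      } else {
        y[top] <- y[top] %% H
      }
    }
    th <- tn %% (2 * pi)

    t1 <- t0 + dt
    if (config$record_density && t1 >= config$record_start &&
        step %% config$record_every == 0L) {
      ix <- pmin(pmax(floor(x / (l / nx)), 0), nx - 1) + 1
      iy <- pmin(pmax(floor(y / (H / ny)), 0), ny - 1) + 1
      for (a in seq_along(ix)) counts[ix[a], iy[a]] <- counts[ix[a], iy[a]] + 1
      n_snapshots <- n_snapshots + 1
    }
  }

  list(event_time = ev_t, event_x = ev_x, counts = counts,
       n_snapshots = n_snapshots, injected = injected, adhered = adhered,
       exited = exited, live = length(x))
}

#' Windowed net adhesion-rate estimate
#'
#' Splits the post-burn-in interval into whole windows (independent
#' replicates, since agents are decoupled), counts adhesion events per
#' window, and reports the mean rate (events per unit dimensionless time
#' over the whole surface) and the SD across windows. With a single window
#' the SD is reported as 0 and flagged undefined.
#'
#' @param events Data frame with columns `time` and `x`; all times must fall
#'   in `[t_burnin, t_end]`.
#' @param config A [sim_config()] object.
#' @return An object of class `adhesion_summary`: list with `events`,
#'   `rate_mean`, `rate_sd`, `sd_defined`, `n_windows`, `window_rates`.
#' @export
net_adhesion_rate <- function(events, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_windows < 1) {
    stop("config error: at least one whole window is required", call. = FALSE)
  }
  if (nrow(events) > 0 &&
      (min(events$time) < config$t_burnin - 1e-9 ||
       max(events$time) > config$t_end + 1e-9)) {
    stop("events must lie within [t_burnin, t_end]", call. = FALSE)
  }
  breaks <- config$t_burnin + config$window_length * (0:config$n_windows)
  idx <- findInterval(events$time, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = config$n_windows)
  rates <- counts / config$window_length
  sd_defined <- config$n_windows > 1
  structure(
    list(events = events[order(events$time), , drop = FALSE],
         rate_mean = mean(rates),
         rate_sd = if (sd_defined) stats::sd(rates) else 0,
         sd_defined = sd_defined,
         n_windows = config$n_windows,
         window_rates = rates),
    class = "adhesion_summary")
}

#' @export
print.adhesion_summary <- function(x, ...) {
  cat(sprintf("Net adhesion rate: %.5g +/- %.3g over %d window(s), %d events\n",
              x$rate_mean, x$rate_sd, x$n_windows, nrow(x$events)))
  invisible(x)
}

#' Inlet density conversion constant
#'
#' Continuum inlet density equivalent to the discrete injection protocol,
#' from equating the injected particle flux `n_inject / dt` with the
#' continuum shear-flow influx `rho H^2 / 2`:
#' `rho_inf = 2 n_inject / (dt H^2)` (cells per unit dimensionless area).
#' Converts simulated event rates to the dimensionless continuum adhesion
#' rate. At the full protocol scale (100 per step, dt = 0.01, H = 1.5) this
#' evaluates to 8.9e3, the conversion constant of the reference protocol.
#'
#' @param config A [sim_config()] object.
#' @return Inlet density (cells per unit area).
#' @export
inlet_density_equivalent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  2 * config$n_inject / (config$dt * config$domain_height^2)
}

#' Normalised occupancy histogram
#'
#' Normalises a position histogram by the expected occupancy of a passive
#' (non-motile) suspension, determined by the domain size, the bin count,
#' and the number of swimmers entering per timestep: far from the depletion
#' layer the normalised density tends to 1, and near-wall depletion shows as
#' values below 1.
#'
#' @param samples Either a two-column matrix/data.frame of pooled `(x, y)`
#'   positions, or a list with `counts` (bins-x by bins-y matrix) and
#'   `n_snapshots` as produced internally by [run_simulation()].
#' @param config A [sim_config()] object.
#' @param bins Length-2 integer vector of bin counts in x and y.
#' @param n_snapshots Number of snapshots pooled in `samples` (when a
#'   position matrix is given).
#' @return An object of class `density_field`: list with `x_edges`,
#'   `y_edges`, `counts`, `normalized`, `n_snapshots`.
#' @export
density_histogram <- function(samples, config, bins = config$bins,
                              n_snapshots = 1) {
  stopifnot(inherits(config, "sim_config"))
  bins <- as.integer(bins)
  if (any(bins < 2)) stop("at least 2 bins per axis required", call. = FALSE)
  l <- config$domain_length
  H <- config$domain_height
  x_edges <- seq(0, l, length.out = bins[1] + 1)
  y_edges <- seq(0, H, length.out = bins[2] + 1)

  if (is.list(samples) && !is.null(samples$counts)) {
    counts <- samples$counts
    n_snapshots <- samples$n_snapshots
    stopifnot(all(dim(counts) == bins))
  } else {
    samples <- as.matrix(samples)
    ix <- pmin(pmax(findInterval(samples[, 1], x_edges,
                                 rightmost.closed = TRUE), 1), bins[1])
    iy <- pmin(pmax(findInterval(samples[, 2], y_edges,
                                 rightmost.closed = TRUE), 1), bins[2])
    counts <- matrix(0, bins[1], bins[2])
    for (a in seq_along(ix)) counts[ix[a], iy[a]] <- counts[ix[a], iy[a]] + 1
  }

  expected <- inlet_density_equivalent(config) *
    (l / bins[1]) * (H / bins[2]) * max(n_snapshots, 1)
  structure(
    list(x_edges = x_edges, y_edges = y_edges, counts = counts,
         normalized = counts / expected, n_snapshots = n_snapshots),
    class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf(
    "Density field: %d x %d bins, %g snapshot(s), far-field mean %.3f\n",
    length(x$x_edges) - 1, length(x$y_edges) - 1, x$n_snapshots,
    mean(x$normalized[, (ncol(x$normalized) %/% 2):ncol(x$normalized)])))
  invisible(x)
}

#' Evolve an orientation ensemble (no walls)
#'
#' Integrates the orientation SDE alone for an ensemble of angles: Jeffery
#' drift plus rotational diffusion, no spatial coupling. Used to check that
#' the long-run simulated angle distribution matches the steady
#' Fokker-Planck solution.
#'
#' @param theta0 Initial angles (radians).
#' @param beta,rot_peclet Shape parameter and rotational Peclet number.
#' @param dt Timestep.
#' @param t_end Integration time.
#' @return Vector of final angles in `[0, 2pi)`.
#' @export
simulate_orientations <- function(theta0, beta, rot_peclet, dt = 1e-2,
                                  t_end = 10) {
  theta_ensemble_cpp(theta0, rot_peclet, beta, dt, round(t_end / dt))
}

#' Write an adhesion event log as CSV
#'
#' @param summary An `adhesion_summary` from [net_adhesion_rate()] or a run.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(summary, path) {
  stopifnot(inherits(summary, "adhesion_summary"))
  utils::write.csv(summary$events, path, row.names = FALSE)
  invisible(path)
}

#' Write a density field as CSV plus a JSON sidecar
#'
#' The CSV holds the normalised density matrix (rows follow x bins, columns
#' y bins); the JSON sidecar records bin edges, snapshot count, and the
#' normalisation constant.
#'
#' @param field A `density_field` object.
#' @param path Output CSV path; the sidecar gets extension `.json`.
#' @param config The generating [sim_config()] (echoed to the sidecar).
#' @return `path`, invisibly.
#' @export
write_density_field <- function(field, path, config = NULL) {
  stopifnot(inherits(field, "density_field"))
  utils::write.table(field$normalized, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(x_edges = field$x_edges, y_edges = field$y_edges,
                  n_snapshots = field$n_snapshots)
  if (!is.null(config)) {
    sidecar$config <- unclass(config)
    sidecar$inlet_density <- inlet_density_equivalent(config)
  }
  jsonlite::write_json(sidecar, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
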