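make_cfg <- function(...) {
  args <- list(rel_swim_speed = 0.05, rot_peclet = 1, beta = 0.5,
               dt = 0.01, domain_height = 0.8, domain_length = 2,
               n_inject = 3, t_end = 30, t_burnin = 10, window_length = 10,
               seed = 42)
  user <- list(...)
  args[names(user)] <- user
  suppressWarnings(do.call(sim_config, args))
}

test_that("config validation catches protocol inconsistencies", {
  expect_error(make_cfg(dt = 0), "dt")
  expect_error(make_cfg(t_burnin = 50), "t_burnin")
  expect_error(make_cfg(window_length = 7), "whole windows")
  expect_warning(sim_config(0.5, 1, 0, domain_height = 0.05,
                            domain_length = 3, n_inject = 1, t_end = 20,
                            t_burnin = 10, window_length = 10),
                 "boundary-layer")
})

test_that("inlet heights follow the flux-weighted distribution", {
  set.seed(77)
  y <- sample_inlet_positions(1e5, 1)
  expect_true(all(y >= 0 & y <= 1))
  # first moment of p(y) = 2y on [0,1] is 2/3
  se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 2 / 3), 3 * se)
  set.seed(5); a <- sample_inlet_positions(10, 2)
  set.seed(5); b <- sample_inlet_positions(10, 2)
  expect_identical(a, b)
})

test_that("the bare step reproduces integrable special cases", {
  # passive tracer rides its streamline exactly for any noise realisation
  cfg <- make_cfg(rel_swim_speed = 0)
  st <- data.frame(x = 0, y = 0.37, theta = 1)
  for (i in 1:200) st <- step_agents(st, cfg)
  expect_equal(st$x, 0.37 * 200 * cfg$dt, tolerance = 1e-12)
  expect_equal(st$y, 0.37, tolerance = 1e-12)

  # noise-free sphere rotates clockwise at half the shear rate
  cfg2 <- make_cfg(beta = 0, rel_swim_speed = 0.1)
  st <- data.frame(x = 0, y = 0.5, theta = 2)
  for (i in 1:500) st <- step_agents(st, cfg2, noise = FALSE)
  expect_equal(st$theta, (2 - 500 * cfg2$dt / 2) %% (2 * pi),
               tolerance = 1e-10)

  # noise-free downward swimmer starting at y = 0.1 with vs = 0.1 reaches
  # the wall at t = 1 up to one timestep
  cfg3 <- make_cfg(rel_swim_speed = 0.1)
  st <- data.frame(x = 0.5, y = 0.1, theta = 3 * pi / 2)
  t_hit <- NA
  for (i in 1:300) {
    st <- step_agents(st, cfg3, noise = FALSE)
    st$theta <- 3 * pi / 2  # held fixed: pure descent diagnostic
    if (st$y <= 0) { t_hit <- i * cfg3$dt; break }
  }
  expect_equal(t_hit, 1, tolerance = cfg3$dt + 1e-12)
})

test_that("compiled and pure-R engines produce identical runs", {
  cfg_c <- make_cfg(record_density = TRUE, bins = c(8L, 8L), engine = "cpp")
  cfg_r <- make_cfg(record_density = TRUE, bins = c(8L, 8L), engine = "r")
  a <- run_simulation(cfg_c)
  b <- run_simulation(cfg_r)
  expect_equal(a$book, b$book)
  expect_equal(nrow(a$summary$events), nrow(b$summary$events))
  expect_equal(a$summary$events$time, b$summary$events$time,
               tolerance = 1e-12)
  expect_equal(a$summary$events$x, b$summary$events$x, tolerance = 1e-12)
  expect_equal(a$density$counts, b$density$counts)
})

test_that("agent bookkeeping is exactly conservative and events are well formed", {
  cfg <- make_cfg(t_end = 40, t_burnin = 10, window_length = 15)
  res <- run_simulation(cfg)
  bk <- res$book
  expect_identical(bk[["injected"]],
                   bk[["adhered"]] + bk[["exited"]] + bk[["live"]])
  ev <- res$summary$events
  expect_true(all(diff(ev$time) >= 0))
  expect_true(all(ev$x >= 0 & ev$x <= cfg$domain_length))
  expect_true(all(ev$time >= cfg$t_burnin & ev$time <= cfg$t_end))

  # passive limit: streamlines never cross the wall, so no adhesion at all
  res0 <- run_simulation(make_cfg(rel_swim_speed = 0))
  expect_equal(res0$book[["adhered"]], 0)
  expect_equal(res0$summary$rate_mean, 0)
})

test_that("windowed rate estimator handles its edge cases", {
  cfg <- make_cfg(t_end = 50, t_burnin = 10, window_length = 40)
  ev <- data.frame(time = c(12, 15, 33), x = c(0.1, 0.5, 1.2))
  s1 <- net_adhesion_rate(ev, cfg)
  expect_equal(s1$rate_mean, 3 / 40)
  expect_equal(s1$rate_sd, 0)
  expect_false(s1$sd_defined)
  expect_equal(s1$n_windows, 1L)

  cfg4 <- make_cfg(t_end = 50, t_burnin = 10, window_length = 10)
  ev4 <- data.frame(time = c(11, 21, 31, 41), x = rep(1, 4))
  s4 <- net_adhesion_rate(ev4, cfg4)
  expect_equal(s4$rate_sd, 0)     # one event per window: zero spread
  expect_true(s4$sd_defined)
  expect_equal(s4$window_rates, rep(0.1, 4))

  expect_error(net_adhesion_rate(data.frame(time = 5, x = 1), cfg4),
               "t_burnin")
})

test_that("histogram normalisation is a fixed point for passive suspensions", {
  cfg <- make_cfg(rel_swim_speed = 0, n_inject = 10, t_end = 120,
                  t_burnin = 40, window_length = 80, record_density = TRUE,
                  record_start = 40, bins = c(6L, 8L))
  res <- run_simulation(cfg)
  nf <- res$density$normalized
  # uniform advected suspension: bins near 1 up to Poisson noise, for
  # streamlines whose transit time l/y fits well inside the burn-in (the
  # near-wall lane y < 0.1 equilibrates only on the timescale l/y)
  expect_lt(max(abs(nf[, 2:8] - 1)), 0.1)
  expect_equal(mean(nf[, 2:8]), 1, tolerance = 0.02)

  # refined bins conserve total counts for a fixed sample set
  set.seed(3)
  pos <- cbind(stats::runif(500, 0, cfg$domain_length),
               stats::runif(500, 0, cfg$domain_height))
  h1 <- density_histogram(pos, cfg, bins = c(5L, 5L))
  h2 <- density_histogram(pos, cfg, bins = c(10L, 10L))
  expect_equal(sum(h1$counts), 500)
  expect_equal(sum(h2$counts), sum(h1$counts))
})

test_that("adhesion depletes the near-wall density below the far field", {
  cfg <- suppressWarnings(sim_config(
    0.01, 1, 0, domain_height = 0.8, domain_length = 3, n_inject = 5,
    t_end = 150, t_burnin = 50, window_length = 100, seed = 12,
    record_density = TRUE, record_every = 2L, bins = c(10L, 40L)))
  res <- run_simulation(cfg)
  nf <- res$density$normalized
  wall <- mean(nf[4:10, 1])       # first y bin, away from the inlet
  far <- mean(nf[, 20:35])
  expect_lt(wall, 0.5)
  expect_equal(far, 1, tolerance = 0.05)
})

test_that("long-run simulated orientations match the steady distribution", {
  pdf <- steady_orientation_pdf(0.88, 1)
  set.seed(61)
  th0 <- sample_orientations(pdf, 1e5)
  th <- simulate_orientations(th0, beta = 0.88, rot_peclet = 1,
                              dt = 5e-3, t_end = 3)
  expect_gt(chisq_angles_p(th, pdf), 0.01)
  # and the sampler itself is distributionally consistent
  expect_gt(chisq_angles_p(th0, pdf), 0.01)
})

test_that("halving the timestep moves the rate by less than the Monte Carlo spread", {
  # injection is per timestep, so rates are compared per unit inlet density
  base <- list(rel_swim_speed = 0.02, rot_peclet = 1, beta = 0,
               domain_height = 0.8, domain_length = 3, n_inject = 4,
               t_end = 250, t_burnin = 50, window_length = 50, seed = 21)
  cfg1 <- suppressWarnings(do.call(sim_config, base))
  r1 <- run_simulation(cfg1)
  base$dt <- 5e-3
  base$seed <- 22
  cfg2 <- suppressWarnings(do.call(sim_config, base))
  r2 <- run_simulation(cfg2)
  m1 <- r1$summary$rate_mean / inlet_density_equivalent(cfg1)
  s1 <- r1$summary$rate_sd / inlet_density_equivalent(cfg1)
  m2 <- r2$summary$rate_mean / inlet_density_equivalent(cfg2)
  s2 <- r2$summary$rate_sd / inlet_density_equivalent(cfg2)
  expect_lt(abs(m1 - m2), sqrt(s1^2 + s2^2))
})
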