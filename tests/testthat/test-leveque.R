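test_that("effective Peclet number matches its closed form and limits", {
  # spherical reduction over a Per grid
  for (per in c(0.1, 1, 2, 10)) {
    g <- dimensionless_groups(0.1, per)
    expect_equal(effective_peclet(g, 0), (4 + per^2) / (2 * per * 0.01),
                 tolerance = 1e-12)
  }
  expect_equal(effective_peclet(dimensionless_groups(0.1, 2), 0), 200)

  # weak-shear limit: ratio to the quiescent Peclet number tends to one
  g <- dimensionless_groups(0.05, 1e-4)
  expect_equal(effective_peclet(g, 0.88) / quiescent_peclet(g), 1,
               tolerance = 1e-6)

  # quiescent limit is flagged as divergent
  expect_error(effective_peclet(dimensionless_groups(0, 1), 0), "quiescent")

  # depends only on the dimensionless groups: rescaling (shear, Dr, Vs, L)
  # jointly leaves it unchanged
  b1 <- bacterium_params(22, 1, 0.88)
  b2 <- bacterium_params(44, 2, 0.88)
  g1 <- dimensionless_groups(b1, flow_params(1, 750))
  g2 <- dimensionless_groups(b2, flow_params(2, 750))
  expect_equal(effective_peclet(g1, 0.88), effective_peclet(g2, 0.88),
               tolerance = 1e-12)
})

test_that("effective diffusivity agrees with the dimensionless form", {
  # identity Deff = shear * L^2 / Peeff over a parameter grid (DT = 0)
  for (vs in c(5, 22)) for (dr in c(0.036, 1)) for (b in c(0, 0.5, 0.88)) {
    bac <- bacterium_params(vs, dr, b)
    for (g in c(0.05, 1, 20)) {
      for (L in c(100, 750)) {
        grp <- dimensionless_groups(bac, flow_params(g, L))
        expect_equal(effective_diffusivity(bac, g),
                     g * L^2 / effective_peclet(grp, b),
                     tolerance = 1e-12)
      }
    }
  }
  # vanishing-shear limit: the quiescent diffusivity (plus DT)
  ecoli <- species_presets("ecoli")
  expect_equal(effective_diffusivity(ecoli, 1e-8),
               quiescent_diffusivity(ecoli) + ecoli$thermal_diffusivity,
               tolerance = 1e-6)
  # spherical simplification 2 Dr Vs^2 / (4 Dr^2 + shear^2)
  bac <- bacterium_params(10, 0.5, 0)
  for (g in c(0.2, 1, 5)) {
    expect_equal(effective_diffusivity(bac, g),
                 2 * 0.5 * 100 / (4 * 0.25 + g^2), tolerance = 1e-12)
  }
})

test_that("boundary-layer orientation is linear in the gradient with the exact coefficient link", {
  g <- dimensionless_groups(0.02, 1.5)
  expect_equal(boundary_layer_orientation(0, g, 0.5, 0.1),
               c(rho_nx = 0, rho_ny = 0))
  # density increasing away from the wall drives swimming toward it
  bl <- boundary_layer_orientation(1, g, 0.5, 0.1)
  expect_lt(bl[["rho_ny"]], 0)
  # vs * |coef_y| / eps^2 * eps^3 = 1/Peeff for random parameter draws
  set.seed(4)
  for (i in 1:20) {
    vs <- stats::runif(1, 1e-3, 0.5)
    per <- stats::runif(1, 0.05, 20)
    beta <- stats::runif(1, 0, 0.95)
    eps <- stats::runif(1, 1e-3, 1)
    grp <- dimensionless_groups(vs, per)
    coef_y <- boundary_layer_orientation(1, grp, beta, eps)[["rho_ny"]]
    expect_equal(vs * abs(coef_y) / eps^2 * eps^3,
                 1 / effective_peclet(grp, beta), tolerance = 1e-12)
  }
})

test_that("similarity density solves the boundary-layer PDE and bounds", {
  peeff <- 300
  expect_equal(density_field(c(0.5, 1, 3), 0, peeff), rep(0, 3))
  expect_equal(density_field(1, 10, peeff), 1, tolerance = 1e-10)
  y <- seq(0, 0.5, length.out = 50)
  rho <- density_field(1, y, peeff)
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho >= 0 & rho <= 1))
  expect_error(density_field(-1, 0.1, peeff), "domain")

  # central-difference PDE residual y rho_x - (1/Pe) rho_yy -> 0 at O(h^2)
  resid <- function(h) {
    x <- 1; yy <- 0.12
    rx <- (density_field(x + h, yy, peeff) -
           density_field(x - h, yy, peeff)) / (2 * h)
    ryy <- (density_field(x, yy + h, peeff) - 2 * density_field(x, yy, peeff) +
            density_field(x, yy - h, peeff)) / h^2
    abs(yy * rx - ryy / peeff)
  }
  r1 <- resid(4e-3); r2 <- resid(2e-3); r3 <- resid(1e-3)
  expect_equal(r1 / r2, 4, tolerance = 0.2)
  expect_equal(r2 / r3, 4, tolerance = 0.2)

  # wall flux of the density field reproduces the closed-form rate
  h <- 1e-7
  for (x in c(0.3, 1, 2.5)) {
    flux <- density_field(x, h, peeff) / h / peeff
    expect_equal(flux, adhesion_rate(x, peeff), tolerance = 1e-6)
  }
})

test_that("local adhesion rate has the classic prefactor and decay", {
  expect_equal(round(3^(1 / 3) / gamma(1 / 3), 3), 0.538)
  expect_equal(adhesion_rate(1, 1), 0.53837, tolerance = 1e-5)
  for (pe in c(1, 50, 2000)) {
    expect_equal(adhesion_rate(8 * 1.7, pe) / adhesion_rate(1.7, pe), 0.5,
                 tolerance = 1e-12)
  }
  expect_error(adhesion_rate(0, 1), "domain")
})

test_that("dimensional adhesion rate nondimensionalises exactly and orders by shape", {
  bac <- bacterium_params(22, 1, 0.88)  # DT = 0 for the exact identity
  for (g in c(0.1, 1, 10)) for (L in c(200, 750)) {
    grp <- dimensionless_groups(bac, flow_params(g, L))
    peeff <- effective_peclet(grp, bac$bretherton)
    x_dim <- 0.4 * L
    expect_equal(dimensional_adhesion_rate(x_dim, bac, g, inlet_density = 1),
                 g * L * adhesion_rate(x_dim / L, peeff), tolerance = 1e-12)
  }
  # linear in the inlet density
  expect_equal(dimensional_adhesion_rate(100, bac, 1, inlet_density = 8),
               8 * dimensional_adhesion_rate(100, bac, 1), tolerance = 1e-12)
  # elongation reduces adhesion at identical motility
  sphere <- bacterium_params(22, 1, 0)
  rod <- bacterium_params(22, 1, 0.88)
  for (g in c(0.5, 2, 20)) {
    expect_gt(dimensional_adhesion_rate(100, sphere, g),
              dimensional_adhesion_rate(100, rod, g))
  }
  # asymptotic log-log slopes +1/3 and -1
  slope <- function(bac, g) {
    h <- 1e-4
    (log(dimensional_adhesion_rate(100, bac, g * exp(h))) -
     log(dimensional_adhesion_rate(100, bac, g * exp(-h)))) / (2 * h)
  }
  expect_equal(slope(rod, 1e-7), 1 / 3, tolerance = 1e-4)
  expect_equal(slope(rod, 1e7), -1, tolerance = 1e-4)
})

test_that("critical shear rate reproduces the species values and scalings", {
  expect_equal(signif(critical_shear(species_presets("ecoli")), 2), 1.1)
  expect_equal(signif(critical_shear(species_presets("paeruginosa")), 2),
               0.039)
  # spherical closed form 2 Dr / sqrt(3), cross-checked by brute force
  for (dr in c(0.2, 1, 3)) {
    bac <- bacterium_params(15, dr, 0)
    gc <- critical_shear(bac)
    expect_equal(gc, 2 * dr / sqrt(3), tolerance = 1e-6)
    expect_equal(gc, grid_max_shear(bac), tolerance = 1e-3)
  }
  # proportional to Dr at fixed shape: species ratio test
  b1 <- bacterium_params(22, 1, 0.88)
  b2 <- bacterium_params(23, 0.036, 0.88)
  expect_equal(critical_shear(b1) / critical_shear(b2), 1 / 0.036,
               tolerance = 1e-6)
})

test_that("adhesion rate is unimodal in shear for valid parameters", {
  set.seed(9)
  bacteria <- c(list(species_presets("ecoli"), species_presets("paeruginosa")),
                lapply(1:5, function(i) {
                  bacterium_params(stats::runif(1, 5, 50),
                                   stats::runif(1, 0.02, 2),
                                   stats::runif(1, 0, 0.95))
                }))
  for (bac in bacteria) {
    g <- exp(seq(log(1e-3 * bac$rot_diffusion), log(1e3 * bac$rot_diffusion),
                 length.out = 400))
    obj <- dimensional_adhesion_rate(100, bac, g)
    ds <- diff(sign(diff(obj)))
    expect_equal(sum(ds != 0), 1)   # single interior extremum
    expect_equal(which(ds != 0) > 1, TRUE)
    expect_gt(max(obj), max(obj[1], obj[length(obj)]))
  }
})

test_that("net adhesion matches quadrature and its scalings", {
  expect_equal(net_adhesion(3, 200),
               stats::integrate(function(x) adhesion_rate(x, 200), 0, 3,
                                rel.tol = 1e-12)$value, tolerance = 1e-10)
  expect_equal(net_adhesion(8 * 1.3, 50) / net_adhesion(1.3, 50), 4,
               tolerance = 1e-12)
  expect_lt(net_adhesion(3, 1e12), 1e-7)
})

test_that("scaled net adhesion collapses across shape and swim speed", {
  l <- 3
  for (per in c(0.3, 1, 4, 20)) {
    vals <- vapply(list(c(0, 0.01), c(0.88, 0.05), c(0.5, 0.002)),
                   function(p) {
                     grp <- dimensionless_groups(p[2], per)
                     scaled_net_adhesion(
                       net_adhesion(l, effective_peclet(grp, p[1])),
                       p[1], grp)
                   }, numeric(1))
    expect_equal(vals[2], vals[1], tolerance = 1e-10)
    expect_equal(vals[3], vals[1], tolerance = 1e-10)
    expect_equal(vals[1], collapse_curve(per, l), tolerance = 1e-10)
  }
  # collapsed curve peaks at Per = 4 and vanishes in both limits
  pers <- exp(seq(log(0.01), log(1000), length.out = 801))
  jb <- collapse_curve(pers, l)
  expect_equal(pers[which.max(jb)], 4, tolerance = 0.02)
  expect_lt(collapse_curve(1e-8, l), 1e-4)
  expect_lt(collapse_curve(1e8, l), 1e-4)
})

test_that("active and quiescent theories agree at low shear and split at high shear", {
  vs <- 0.01
  ratio <- function(per) {
    g <- dimensionless_groups(vs, per)
    (quiescent_peclet(g) / effective_peclet(g, 0.88))^(2 / 3)
  }
  expect_equal(ratio(1e-4), 1, tolerance = 1e-4)
  expect_lt(ratio(1e4), 1e-3)
})

test_that("regime classification follows its thresholds and precedence", {
  expect_equal(classify_regime(dimensionless_groups(1.5, 1), 0)$label, "A")
  # slow swimmers: D just below the body-length line; at extreme slowness
  # the depletion layer is thinner than a body, so B takes precedence
  expect_equal(classify_regime(dimensionless_groups(2e-4, 1), 0)$label, "D")
  expect_equal(classify_regime(dimensionless_groups(1e-9, 1), 0)$label, "B")
  # B: depletion layer thinner than a cell body (needs a huge Peeff at
  # vs < 1, i.e. extreme Per); takes precedence over C
  g_b <- dimensionless_groups(0.9, 2e10)
  expect_lte(effective_peclet(g_b, 0)^(-1 / 3), 5e-4)
  expect_equal(classify_regime(g_b, 0)$label, "B")
  # C: Per beyond 1/eps_body while the layer is still thicker than a body
  g_c <- dimensionless_groups(0.3, 5000)
  expect_gt(effective_peclet(g_c, 0)^(-1 / 3), 5e-4)
  expect_equal(classify_regime(g_c, 0)$label, "C")
  # the reference demonstration point lies in the valid region
  expect_equal(classify_regime(dimensionless_groups(0.01, 1), 0)$label,
               "VALID")
  # E. coli in a small catheter at mid-range shear: inside the valid region
  ecoli <- species_presets("ecoli")
  sc <- scenario_presets("small_catheter")
  g_mid <- sqrt(sc$shear_lo * sc$shear_hi)
  grp <- dimensionless_groups(ecoli, flow_params(g_mid, sc$lengthscale))
  expect_equal(classify_regime(grp, ecoli$bretherton)$label, "VALID")
  # precedence: a point with vs >= 1 is A no matter how extreme Per is
  expect_equal(classify_regime(dimensionless_groups(2, 1e6), 0)$label, "A")
  expect_equal(classify_regime(dimensionless_groups(2, 1e-6), 0.9)$label, "A")
})
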