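#' Shear-rate sweep comparing simulation and theory
#'
#' Runs one agent-based simulation per shear rate for a given species,
#' computes the matching closed-form predictions, applies the net-adhesion
#' scaling collapse to both, and classifies the validity regime. The
#' dimensional net adhesion rate is reported as `rate_mean * shear_rate`
#' (events/s over the whole surface), the convention used for adhesion-rate
#' curves against shear rate.
#'
#' @param species A [bacterium_params()] object or a preset name for
#'   [species_presets()].
#' @param shear_grid Strictly increasing shear rates (1/s).
#' @param sim_preset Preset name passed to [sim_preset()].
#' @param lengthscale Flow lengthscale `L` in um (default 750).
#' @param seed Root seed; point `i` runs with `seed + i - 1`.
#' @param ... Overrides for [sim_preset()] (e.g. `n_inject`, `t_end`).
#' @return A `sweep_result` data frame, one row per grid point, with
#'   simulated and theoretical rates, scaled net adhesion, regime label,
#'   per-point seed, and a config hash; failed points are flagged `ok =
#'   FALSE` and the attribute `exit_status` is nonzero if any failed.
#' @export
sweep_shear <- function(species, shear_grid,
                        sim_preset = "adhesion_reduced",
                        lengthscale = 750, seed = 1, ...) {
  if (is.character(species)) species <- species_presets(species)
  stopifnot(inherits(species, "bacterium_params"))
  if (any(diff(shear_grid) <= 0)) {
    stop("shear_grid must be strictly increasing", call. = FALSE)
  }
  preset_name <- sim_preset
  extra <- list(...)

  rows <- lapply(seq_along(shear_grid), function(i) {
    g <- shear_grid[i]
    groups <- dimensionless_groups(species,
                                   flow_params(g, lengthscale))
    peeff <- effective_peclet(groups, species$bretherton)
    point_seed <- seed + i - 1L
    row <- data.frame(
      shear_rate = g,
      vs = groups$rel_swim_speed, per = groups$rot_peclet,
      rate_mean = NA_real_, rate_sd = NA_real_, rate_dim = NA_real_,
      theory_rate = NA_real_, theory_rate_dim = NA_real_,
      jbar_sim = NA_real_, jbar_sim_sd = NA_real_, jbar_theory = NA_real_,
      regime = classify_regime(groups, species$bretherton)$label,
      seed = point_seed, config_hash = NA_character_, ok = FALSE)
    out <- tryCatch({
      cfg <- do.call("sim_preset",
                     c(list(preset_name,
                            rel_swim_speed = groups$rel_swim_speed,
                            rot_peclet = groups$rot_peclet,
                            beta = species$bretherton, seed = point_seed),
                       extra))
      res <- suppressWarnings(run_simulation(cfg))
      rho <- inlet_density_equivalent(cfg)
      l <- cfg$domain_length
      row$rate_mean <- res$summary$rate_mean
      row$rate_sd <- res$summary$rate_sd
      row$rate_dim <- res$summary$rate_mean * g
      row$theory_rate <- rho * net_adhesion(l, peeff)
      row$theory_rate_dim <- row$theory_rate * g
      row$jbar_sim <- scaled_net_adhesion(res$summary$rate_mean,
                                          species$bretherton, groups, rho)
      row$jbar_sim_sd <- scaled_net_adhesion(
        res$summary$rate_sd / sqrt(res$summary$n_windows),
        species$bretherton, groups, rho)
      row$jbar_theory <- collapse_curve(groups$rot_peclet, l)
      row$config_hash <- config_hash(cfg, drop_seed = TRUE)
      row$ok <- TRUE
      row
    }, error = function(e) {
      warning(sprintf("sweep point shear_rate = %g failed: %s", g,
                      conditionMessage(e)), call. = FALSE)
      row
    })
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "exit_status") <- if (all(out$ok)) 0L else 3L
  attr(out, "species") <- species
  attr(out, "lengthscale") <- lengthscale
  out
}

# Stable hash of a configuration (seed optionally dropped so all rows of a
# sweep share one hash).
config_hash <- function(config, drop_seed = FALSE) {
  x <- unclass(config)
  if (drop_seed) x$seed <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Compare a simulated density field with the similarity solution
#'
#' Evaluates the closed-form near-wall density at bin centres and reports
#' (i) the mean absolute deviation from the normalised histogram outside an
#' exclusion zone near the inlet corner (where an additional boundary layer,
#' not modelled by the similarity solution, lives) and (ii) the simulated
#' and theoretical 50-percent-density contours and their maximum gap in
#' units of y-bins.
#'
#' @param field A `density_field` from [density_histogram()] /
#'   [run_simulation()].
#' @param peeff Effective Peclet number of the matching theory.
#' @param exclusion_x Exclude bins with centre `x` below this (dimensionless).
#' @return List with `mad`, `contour` (data frame `x`, `y_sim`, `y_theory`,
#'   `gap_bins`), `max_gap_bins`.
#' @export
compare_density <- function(field, peeff, exclusion_x = 0.5) {
  stopifnot(inherits(field, "density_field"))
  if (is.null(field$normalized)) stop("field must be normalised",
                                      call. = FALSE)
  xc <- (field$x_edges[-1] + field$x_edges[-length(field$x_edges)]) / 2
  yc <- (field$y_edges[-1] + field$y_edges[-length(field$y_edges)]) / 2
  dy <- diff(field$y_edges[1:2])
  keep <- xc >= exclusion_x

  theo <- outer(xc, yc, function(x, y) density_field(x, y, peeff))
  mad <- mean(abs(field$normalized[keep, ] - theo[keep, ]))

  z_half <- stats::qgamma(0.5, 1 / 3)
  contour_rows <- lapply(which(keep), function(i) {
    prof <- field$normalized[i, ]
    y_sim <- contour_crossing(yc, prof, 0.5)
    y_th <- (9 * xc[i] * z_half / peeff)^(1 / 3)
    data.frame(x = xc[i], y_sim = y_sim, y_theory = y_th,
               gap_bins = abs(y_sim - y_th) / dy)
  })
  contour <- do.call(rbind, contour_rows)
  list(mad = mad, contour = contour,
       max_gap_bins = max(contour$gap_bins, na.rm = TRUE))
}

# First upward crossing of `level` in a wall-normal profile, linearly
# interpolated between bin centres.
contour_crossing <- function(y, profile, level) {
  above <- profile >= level
  if (all(above)) return(y[1])
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(y[1])
  y0 <- y[i - 1]; y1 <- y[i]
  p0 <- profile[i - 1]; p1 <- profile[i]
  if (p1 == p0) return(y1)
  y0 + (level - p0) / (p1 - p0) * (y1 - y0)
}

#' Validity-regime map over dimensionless parameter space
#'
#' Evaluates the effective Peclet number and the regime label on a grid of
#' relative swimming speed and rotational Peclet number, and overlays the
#' built-in species/scenario combinations as marker records (each scenario
#' contributes its two shear-rate endpoints per species).
#'
#' @param vs_grid,per_grid Positive grids of `vs` and `Per`.
#' @param beta Bretherton shape parameter used for the map.
#' @param eps_threshold Region-B threshold (see [classify_regime()]).
#' @return A `regime_map` data frame with columns `vs`, `per`, `peeff`,
#'   `label`; species/scenario markers in attribute `markers`.
#' @export
regime_map <- function(vs_grid, per_grid, beta = 0, eps_threshold = 5e-4) {
  stopifnot(all(vs_grid > 0), all(per_grid > 0))
  grid <- expand.grid(vs = vs_grid, per = per_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    groups <- dimensionless_groups(grid$vs[i], grid$per[i])
    lab <- classify_regime(groups, beta, eps_threshold)
    data.frame(vs = grid$vs[i], per = grid$per[i],
               peeff = effective_peclet(groups, beta), label = lab$label)
  })
  out <- do.call(rbind, res)

  markers <- list()
  for (sp_name in names(species_presets())) {
    sp <- species_presets(sp_name)
    for (sc_name in names(scenario_presets())) {
      sc <- scenario_presets(sc_name)
      for (g in c(sc$shear_lo, sc$shear_hi)) {
        gr <- dimensionless_groups(sp, flow_params(g, sc$lengthscale))
        markers[[length(markers) + 1]] <- data.frame(
          species = sp_name, scenario = sc_name, shear_rate = g,
          vs = gr$rel_swim_speed, per = gr$rot_peclet,
          label = classify_regime(gr, sp$bretherton, eps_threshold)$label)
      }
    }
  }
  class(out) <- c("regime_map", "data.frame")
  attr(out, "markers") <- do.call(rbind, markers)
  attr(out, "beta") <- beta
  out
}

#' Write a regime map as CSV and JSON records
#'
#' @param map A [regime_map()] result.
#' @param path Output CSV path; JSON records get extension `.json`.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  stopifnot(inherits(map, "regime_map"))
  con <- file(path, "w")
  writeLines(sprintf("# beta = %.17g", attr(map, "beta")), con)
  utils::write.csv(as.data.frame(map), con, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    lapply(seq_len(nrow(map)), function(i) {
      list(Vs = map$vs[i], Per = map$per[i], Peeff = map$peeff[i],
           label = map$label[i])
    }),
    sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sweep result as CSV with a manifest
#'
#' The CSV carries one row per sweep point; the JSON manifest records the
#' package version, root seed, species parameters, and output checksums, so
#' a sweep can be re-run and compared bit for bit (deterministic columns)
#' or statistically (same-seed stochastic columns are identical too).
#'
#' @param sweep A [sweep_shear()] result.
#' @param path Output CSV path; the manifest gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  sp <- attr(sweep, "species")
  manifest <- list(
    package = "activeLeveque",
    version = as.character(utils::packageVersion("activeLeveque")),
    species = unclass(sp),
    lengthscale = attr(sweep, "lengthscale"),
    seeds = sweep$seed,
    exit_status = attr(sweep, "exit_status"),
    csv_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(manifest, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
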