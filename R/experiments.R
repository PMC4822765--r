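# Fixed simulation experiments that validate the pipeline against the
# generator's known ground truth: chi-square calibration/power of the
# barrier test, recovery of the planted habitat-preference ranking, and
# recovery of the crossing half-width. The same experiment definitions are
# used by the test suite and by scripts/acceptance.R so the study conditions
# are stated in exactly one place.

#' Nearest land cell center to a point
#'
#' @param r a [habitat_raster()].
#' @param x,y desired location (m).
#' @return c(x, y) of the closest non-Water cell center.
#' @export
nearest_land <- function(r, x, y) {
  water <- match("Water", r$classes)
  land <- which(r$values != water)
  if (length(land) == 0) stop("landscape has no land")
  iy <- (land - 1) %% nrow(r$values) + 1
  ix <- (land - 1) %/% nrow(r$values) + 1
  px <- r$xmin + (ix - 0.5) * r$cell
  py <- r$ymin + (iy - 0.5) * r$cell
  k <- which.min((px - x)^2 + (py - y)^2)
  c(px[k], py[k])
}

# Channels-only landscape for the barrier experiments: corridors whose
# widths span the creek-to-river range a mangrove tiger encounters, at
# seed-jittered positions/orientations. ~15% water keeps the whole-path
# rejection sampler for null trajectories feasible.
barrier_experiment_landscape <- function(seed, extent = 10000, cell = 50,
                                         widths = c(30, 50, 80, 120, 180,
                                                    250, 350, 500)) {
  set.seed(seed)
  n <- length(widths)
  diag_len <- extent * 2
  pos <- stats::runif(n, 0.15 * extent, 0.85 * extent)
  vert <- seq_len(n) %% 2 == 0
  jit <- stats::runif(n, -0.2, 0.2)  # slope jitter
  x0 <- ifelse(vert, pos - jit * diag_len, -extent / 2)
  x1 <- ifelse(vert, pos + jit * diag_len, extent * 1.5)
  y0 <- ifelse(vert, -extent / 2, pos - jit * diag_len)
  y1 <- ifelse(vert, extent * 1.5, pos + jit * diag_len)
  channels <- channel_set(x0, y0, x1, y1, widths)
  nx <- extent / cell
  vals <- matrix(2L, nrow = nx, ncol = nx)  # Phoenix everywhere
  xc <- (seq_len(nx) - 0.5) * cell
  XX <- rep(xc, each = nx); YY <- rep(xc, times = nx)
  vals[matrix(point_in_channels(XX, YY, channels), nrow = nx)] <- 1L
  list(raster = habitat_raster(vals, 0, 0, cell), channels = channels)
}

# Tiger spec matched to the null-path family for calibration runs: uniform
# headings, uniform step lengths, no home attraction, flat activity, no
# habitat preference on land, water endpoints effectively forbidden (as
# null-path nodes are). Under crossing_halfwidth = Inf the walker then obeys
# the null hypothesis the chi-square test states.
barrier_experiment_spec <- function(home, halfwidth, days, seed) {
  tiger_sim_spec(
    animal_id = "calib",
    home_center = home,
    attraction_strength = 0,
    step_scale = 200,
    step_length_dist = "uniform",
    turning_concentration = 0,
    habitat_weights = c(Water = 1e-9, Phoenix = 1, Ceriops = 1,
                        Barren = 1, AvicSonn = 1),
    crossing_halfwidth = halfwidth,
    activity_profile = rep(1, 24),
    fix_interval_hours = 1L,
    fix_success_prob = 1,
    duration_days = days,
    seed = seed)
}

#' One replicate of the channel-barrier test on simulated data
#'
#' Simulates several tigers with scattered home centers and the given
#' crossing half-width on a channels-only landscape, detects observed
#' crossings over the usable daily paths, generates `n_null` random-walk
#' null paths per day inside the pooled common polygon (as the field design
#' does: the availability polygon spans every animal's fixes, so null paths
#' traverse the channels that separate territories), and runs
#' [crossing_chisq()].
#'
#' @param seed replicate seed (drives the landscape, the tigers and the null
#'   paths).
#' @param crossing_halfwidth half-width (m) of the simulated reluctance;
#'   `Inf` disables reluctance (the null hypothesis is then true).
#' @param n_days total simulated days, split over `n_animals` (60-day null
#'   arm by default).
#' @param n_null null paths per observed daily path.
#' @param n_animals number of simulated tigers pooled into the common
#'   polygon.
#' @param walker "matched" moves like the null-path family (uniform headings
#'   and step lengths, no home attraction) so that with no reluctance the
#'   null hypothesis is as close to exactly true as the design permits — the
#'   type-I arm; "study" uses the simulator's study-condition movement (home
#'   attraction, gamma steps, dawn activity), whose territories anchor
#'   between channels as real home ranges do — the power arm.
#' @return List: `p`, `chi_square`, `df`, `n_observed`, `n_null_crossings`,
#'   `mean_crossings_per_day`.
#' @export
barrier_test_replicate <- function(seed, crossing_halfwidth = Inf,
                                   n_days = 60, n_null = 5, n_animals = 4,
                                   walker = c("matched", "study")) {
  walker <- match.arg(walker)
  land <- barrier_experiment_landscape(seed)
  ext <- raster_extent(land$raster)
  w <- ext[2] - ext[1]; h <- ext[4] - ext[3]
  spots <- cbind(ext[1] + c(0.25, 0.75, 0.25, 0.75, 0.5) * w,
                 ext[3] + c(0.25, 0.25, 0.75, 0.75, 0.5) * h)
  days_per <- ceiling(n_days / n_animals)
  sims <- lapply(seq_len(n_animals), function(a) {
    home <- nearest_land(land$raster, spots[(a - 1) %% 5 + 1, 1],
                         spots[(a - 1) %% 5 + 1, 2])
    spec <- if (walker == "matched")
      barrier_experiment_spec(home, crossing_halfwidth, days_per,
                              seed + a)
    else
      # fix_success = 1: crossing detection from complete hourly fixes
      # matches the field workflow of digitizing whole daily trajectories;
      # dropout would put multi-hour straight chords through channels the
      # animal never crossed
      tiger_sim_spec(animal_id = paste0("T", a), home_center = home,
                     habitat_weights = c(Water = 1e-9, Phoenix = 1,
                                         Ceriops = 1, Barren = 1,
                                         AvicSonn = 1),
                     crossing_halfwidth = crossing_halfwidth,
                     fix_success_prob = 1, duration_days = days_per,
                     seed = seed + a)
    simulate_tiger(spec, land)
  })
  days <- list()
  for (s in sims)
    for (p in assemble_daily_paths(s$trajectory, min_fixes = 12))
      if (p$usable) days[[length(days) + 1L]] <- p
  poly <- common_polygon(lapply(sims, `[[`, "trajectory"))
  obs <- do.call(rbind, lapply(days, detect_crossings,
                               channels = land$channels))
  set.seed(seed + 1001L)
  nul <- list()
  for (i in seq_along(days)) {
    paths <- generate_null_paths(days[[i]], n = n_null, polygon = poly,
                                 landscape = land, allow_partial = TRUE)
    for (j in seq_along(paths)) {
      nul[[length(nul) + 1L]] <- detect_crossings(
        paths[[j]], land$channels,
        path_id = paste0("null", i, "_", j), source = "null")
    }
  }
  recs <- rbind(obs, do.call(rbind, nul))
  tab <- bin_crossings(recs)
  ct <- crossing_chisq(tab)
  list(p = ct$p, chi_square = ct$chi_square, df = ct$df,
       n_observed = sum(tab$observed),
       n_null_crossings = sum(tab$availability),
       mean_crossings_per_day = sum(tab$observed) / length(days))
}

#' Rejection rate of the barrier test over replicates
#'
#' @param n_reps number of replicate runs.
#' @param crossing_halfwidth simulated reluctance half-width (m); Inf = none.
#' @param seed base seed; replicate r uses `seed + 1000 * r`.
#' @param n_days,n_null,n_animals,walker passed to
#'   [barrier_test_replicate()].
#' @param alpha significance level.
#' @return List: `rejection_rate` (over replicates where the test was
#'   computable), `p_values` (NA where a replicate yielded too few crossings
#'   to test).
#' @export
barrier_test_experiment <- function(n_reps = 100, crossing_halfwidth = Inf,
                                    seed = 1, n_days = 60, n_null = 5,
                                    n_animals = 4,
                                    walker = c("matched", "study"),
                                    alpha = 0.05) {
  walker <- match.arg(walker)
  ps <- vapply(seq_len(n_reps), function(r) {
    tryCatch(
      barrier_test_replicate(seed + 1000L * r, crossing_halfwidth,
                             n_days = n_days, n_null = n_null,
                             n_animals = n_animals, walker = walker)$p,
      error = function(e) NA_real_)
  }, 0)
  list(rejection_rate = mean(ps < alpha, na.rm = TRUE), p_values = ps)
}

# Weights planting the preference order AvicSonn > Phoenix > Ceriops >
# Barren > Water with factor-2 separation between adjacent ranks.
planted_weights <- function() {
  c(Water = 0.25, Phoenix = 4, Ceriops = 2, Barren = 1, AvicSonn = 8)
}

#' One replicate of the habitat-preference recovery study
#'
#' Generates a landscape, simulates `n_animals` tigers sharing a planted
#' habitat-weight ranking, runs the full use/availability pipeline (use =
#' fix class shares; availability = class shares of the 95% fixed-kernel
#' home range) and the compositional analysis.
#'
#' @param seed replicate seed.
#' @param n_animals number of simulated animals (samples).
#' @param duration_days tracking days per animal.
#' @param weights planted habitat weights (named, positive); the default
#'   plants AvicSonn > Phoenix > Ceriops > Barren > Water.
#' @return List: `result` (a `compositional_result`), `planted_order`,
#'   `recovered` (logical: full order matched).
#' @export
preference_recovery_replicate <- function(seed, n_animals = 6,
                                          duration_days = 20,
                                          weights = planted_weights()) {
  lspec <- landscape_spec(extent_m = c(15000, 15000), cell_size = 50,
                          channel_count = 5, width_range = c(30, 600),
                          seed = seed)
  land <- generate_landscape(lspec)
  ext <- raster_extent(land$raster)
  set.seed(seed + 7L)
  centers <- cbind(stats::runif(n_animals, ext[1] + 2500, ext[2] - 2500),
                   stats::runif(n_animals, ext[3] + 2500, ext[4] - 2500))
  samples <- list()
  for (a in seq_len(n_animals)) {
    home <- nearest_land(land$raster, centers[a, 1], centers[a, 2])
    spec <- tiger_sim_spec(animal_id = paste0("T", a), home_center = home,
                           habitat_weights = weights,
                           duration_days = duration_days,
                           fix_success_prob = 1,
                           seed = seed + 13L * a)
    sim <- simulate_tiger(spec, land)
    ud <- compute_fixed_kernel_ud(sim$trajectory, h = 1000)
    hr95 <- fk_home_range(ud, level = 95, animal_id = spec$animal_id)
    u <- habitat_use(sim$trajectory, land$raster)
    av <- habitat_availability(hr95, land$raster)
    av[av == 0] <- 1e-6  # guard: a class absent from one home range
    av <- av / sum(av)
    samples[[a]] <- use_avail_sample(spec$animal_id, u, av)
  }
  res <- compositional_analysis(do.call(rbind, samples))
  planted <- names(sort(weights, decreasing = TRUE))
  list(result = res, planted_order = planted,
       recovered = identical(res$ranking, planted))
}

#' Recovery rate of the planted preference order over replicates
#'
#' @param n_reps replicates.
#' @param seed base seed.
#' @param ... passed to [preference_recovery_replicate()].
#' @return List: `recovery_rate`, `df_values` (test degrees of freedom per
#'   replicate), `recovered` logical vector.
#' @export
preference_recovery_experiment <- function(n_reps = 100, seed = 1, ...) {
  rec <- logical(n_reps)
  dfs <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    out <- preference_recovery_replicate(seed + 1000L * r, ...)
    rec[r] <- out$recovered
    dfs[r] <- out$result$df
  }
  list(recovery_rate = mean(rec), df_values = dfs, recovered = rec)
}

#' Estimate the crossing half-width from simulation truth
#'
#' Per channel, the realized acceptance ratio of crossing proposals is
#' `accepted / proposed`; under the generator's model its logarithm is linear
#' in channel width with slope `-ln(2) / halfwidth`. A weighted linear fit of
#' log acceptance on width recovers the half-width.
#'
#' @param truth the `truth` element of [simulate_tiger()].
#' @param channels the [channel_set()] of the landscape.
#' @param min_proposals channels with fewer crossing proposals are dropped.
#' @return Estimated half-width (m).
#' @export
estimate_crossing_halfwidth <- function(truth, channels, min_proposals = 20) {
  prop <- truth$crossing_proposals
  acc <- truth$crossing_accepts
  keep <- prop >= min_proposals & acc > 0
  if (sum(keep) < 3) stop("too few channels with enough crossing proposals")
  w <- channels$width_m[match(names(prop)[keep], channels$id)]
  ratio <- acc[keep] / prop[keep]
  fit <- stats::lm(log(ratio) ~ w, weights = prop[keep])
  slope <- stats::coef(fit)["w"]
  if (slope >= 0) return(Inf)
  unname(-log(2) / slope)
}
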