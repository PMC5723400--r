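# Synthetic-data generators: clonal populations sampled in a 50-m plot,
# parametric storm histories, and covariate-response scenarios for the
# driver analysis. Every generator records the truth it drew, so tests can
# check recovery without inferring truth from the data.

#' Draw Dirichlet-distributed allele frequencies for a locus panel
#'
#' Frequencies per locus are drawn from a symmetric Dirichlet; the default
#' allele counts mirror a 7-locus microsatellite panel with 2 to 12 alleles
#' per locus.
#'
#' @param n_alleles Integer vector of allele counts, one per locus.
#' @param concentration Dirichlet concentration parameter (default 1,
#'   uniform over the simplex).
#' @return Named list of named frequency vectors (alleles `a01`, `a02`,
#'   ...), one per locus `L01`, `L02`, ...
#' @export
simulate_locus_frequencies <- function(n_alleles = c(12, 2, 12, 7, 5, 7, 3),
                                       concentration = 1) {
  out <- lapply(n_alleles, function(k) {
    g <- stats::rgamma(k, shape = concentration)
    p <- g / sum(g)
    names(p) <- sprintf("a%02d", seq_len(k))
    p
  })
  names(out) <- sprintf("L%02d", seq_along(out))
  out
}

#' Simulate a clonal seagrass population and its ramet sampling
#'
#' Emulates the field design: `n_samples` ramet samples collected inside a
#' circular plot of `plot_diameter` metres, each sample at least
#' `min_spacing` metres from every other. `g_true` genets are placed
#' uniformly in the plot; a sample point is kept only if it falls within
#' `ramet_radius` of some genet (otherwise redrawn) and is assigned to the
#' nearest genet. Each genet carries one true multilocus genotype drawn
#' once under Hardy-Weinberg equilibrium from the locus allele
#' frequencies; missing calls are injected per call at `missing_rate`.
#'
#' @param g_true Number of genets in the plot.
#' @param loci Named list of per-locus allele-frequency vectors (see
#'   [simulate_locus_frequencies()]); default draws the 7-locus
#'   microsatellite panel.
#' @param n_samples Samples collected (default 50).
#' @param min_spacing Minimum distance between samples, m (default 2).
#' @param plot_diameter Plot diameter, m (default 50).
#' @param ramet_radius Maximum distance a ramet can lie from its genet
#'   center, m (default 15).
#' @param missing_rate Per-call missing probability (default 0).
#' @param site_id,species Labels carried into the genotype matrix.
#' @param seed Optional RNG seed (`set.seed`) for reproducibility.
#' @param max_tries Candidate draws before the packing is declared
#'   infeasible.
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`:
#'   `genet_xy`, `sample_xy`, `sample_genet` (index per sample),
#'   `genet_genotypes` (list of 2 x L allele matrices), `g_sampled`
#'   (distinct genets actually sampled), `g_sampled_distinct` (distinct
#'   true multilocus genotypes among sampled genets), and `seed`.
#' @export
simulate_clonal_population <- function(g_true,
                                       loci = simulate_locus_frequencies(),
                                       n_samples = 50L, min_spacing = 2,
                                       plot_diameter = 50,
                                       ramet_radius = 15,
                                       missing_rate = 0,
                                       site_id = "site1",
                                       species = "synthetic",
                                       seed = NULL,
                                       max_tries = 200L * n_samples) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(g_true >= 1L, n_samples >= 1L, min_spacing >= 0,
            missing_rate >= 0, missing_rate < 1)
  radius <- plot_diameter / 2
  runif_disc <- function(n) {
    r <- radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  }
  genet_xy <- runif_disc(g_true)
  sample_xy <- matrix(numeric(0), ncol = 2)
  sample_genet <- integer(0)
  tries <- 0L
  while (nrow(sample_xy) < n_samples) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: could not place ", n_samples,
           " samples at >= ", min_spacing, " m spacing within ",
           ramet_radius, " m of a genet in a ", plot_diameter,
           "-m plot after ", max_tries, " tries")
    pt <- runif_disc(1L)
    if (nrow(sample_xy) > 0L) {
      d2 <- (sample_xy[, 1] - pt[1])^2 + (sample_xy[, 2] - pt[2])^2
      if (min(d2) < min_spacing^2) next
    }
    dg <- sqrt((genet_xy[, 1] - pt[1])^2 + (genet_xy[, 2] - pt[2])^2)
    if (min(dg) > ramet_radius) next  # unoccupied ground; redraw
    sample_xy <- rbind(sample_xy, pt)
    sample_genet <- c(sample_genet, which.min(dg))
  }
  # one true genotype per genet, drawn under HWE
  genet_genotypes <- lapply(seq_len(g_true), function(i) {
    vapply(loci, function(p) {
      sort(sample(names(p), 2L, replace = TRUE, prob = p))
    }, character(2))
  })
  a1 <- t(vapply(sample_genet, function(gi) genet_genotypes[[gi]][1L, ],
                 character(length(loci))))
  a2 <- t(vapply(sample_genet, function(gi) genet_genotypes[[gi]][2L, ],
                 character(length(loci))))
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(length(a1)) < missing_rate, nrow(a1))
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
  }
  sample_ids <- sprintf("r%03d", seq_len(n_samples))
  g <- genotype_matrix(site_id, species, sample_ids, names(loci), a1, a2)
  sampled <- unique(sample_genet)
  keys <- vapply(genet_genotypes[sampled], function(m)
    paste(m[1L, ], m[2L, ], sep = "/", collapse = "|"), character(1))
  list(genotypes = g,
       truth = list(genet_xy = genet_xy, sample_xy = sample_xy,
                    sample_genet = sample_genet,
                    genet_genotypes = genet_genotypes,
                    g_sampled = length(sampled),
                    g_sampled_distinct = length(unique(keys)),
                    loci = loci, seed = seed))
}

#' Storm-scenario parameters
#'
#' Parameters of the parametric storm generator: a Poisson storm arrival
#' process, straight-line tracks, a radially decaying vortex wind profile
#' (linear rise to the maximum wind at the radius of maximum winds, power
#' decay beyond), i.i.d. Weibull synoptic winds, and a monotone
#' wind-to-wave map. The vortex is a deliberately simple stand-in whose
#' only contract is hourly winds at a site.
#'
#' @param storms_per_year Poisson rate of storm arrivals.
#' @param vmax Maximum cyclone wind speed, m/s.
#' @param rmw Radius of maximum winds, km.
#' @param decay Power-law decay exponent of wind beyond `rmw`.
#' @param track_speed Storm translation speed, km/h.
#' @param duration_hours Hours each storm is tracked.
#' @param genesis_radius Storms start uniformly within this distance of the
#'   region center, km.
#' @param synoptic_shape,synoptic_scale Weibull parameters of the synoptic
#'   wind, m/s.
#' @param wave_model Wind-to-significant-wave-height map (default
#'   [default_wave_model()]).
#' @return A list of class `storm_scenario`.
#' @export
storm_scenario <- function(storms_per_year = 2, vmax = 50, rmw = 30,
                           decay = 0.7, track_speed = 20,
                           duration_hours = 72, genesis_radius = 500,
                           synoptic_shape = 2, synoptic_scale = 8,
                           wave_model = default_wave_model()) {
  structure(list(storms_per_year = storms_per_year, vmax = vmax, rmw = rmw,
                 decay = decay, track_speed = track_speed,
                 duration_hours = duration_hours,
                 genesis_radius = genesis_radius,
                 synoptic_shape = synoptic_shape,
                 synoptic_scale = synoptic_scale,
                 wave_model = wave_model),
            class = "storm_scenario")
}

# vortex wind speed (m/s) at radial distance r (km)
vortex_wind <- function(r, vmax, rmw, decay) {
  ifelse(r <= rmw, vmax * r / rmw, vmax * (rmw / r)^decay)
}

#' Simulate an hourly storm-wind history at study sites
#'
#' Storms arrive as a Poisson process in time; each follows a straight
#' great-circle track at constant speed past the region, and hourly cyclone
#' winds at each site come from the radially decaying vortex. Synoptic
#' winds are drawn i.i.d. from the scenario's Weibull distribution. Only
#' storm-active hours are emitted (quiet hours never reach the wave
#' criterion and are treated as below threshold downstream); overlapping
#' storms at a site keep the stronger wind.
#'
#' @param scenario A [storm_scenario()].
#' @param years Number of years simulated.
#' @param sites Data frame with columns `site_id`, `lat`, `lon` (WGS84
#'   decimal degrees).
#' @param start_year First calendar year (default 1985).
#' @param seed Optional RNG seed.
#' @return A list with `series` (named list per site of [exposure_events()]
#'   -ready data frames with `timestamp`, `site_id`, `cyclone_wind`,
#'   `synoptic_wind`, `distance_to_center`, `eye_radius`), `years`
#'   (calendar years covered), and `truth` (`storm_starts`, per-year storm
#'   counts, `scenario`, `seed`).
#' @export
simulate_storm_history <- function(scenario, years, sites,
                                   start_year = 1985L, seed = NULL) {
  stopifnot(inherits(scenario, "storm_scenario"), years >= 1L,
            all(c("site_id", "lat", "lon") %in% names(sites)))
  if (!is.null(seed)) set.seed(seed)
  yr <- seq(start_year, length.out = years)
  n_storms <- stats::rpois(years, scenario$storms_per_year)
  center <- c(mean(sites$lon), mean(sites$lat))
  origin <- as.POSIXct(paste0(start_year, "-01-01 00:00:00"), tz = "UTC")
  per_site <- lapply(seq_len(nrow(sites)), function(i) list())
  storm_starts <- list()
  for (y in seq_len(years)) {
    for (s in seq_len(n_storms[y])) {
      # genesis point and heading
      bearing0 <- stats::runif(1, 0, 360)
      dist0 <- scenario$genesis_radius * sqrt(stats::runif(1))
      p0 <- geosphere::destPoint(center, bearing0, dist0 * 1000)
      heading <- stats::runif(1, 0, 360)
      t0 <- origin + ((yr[y] - start_year) * 365.25 * 24 +
                        stats::runif(1, 0, 364 * 24)) * 3600
      t0 <- trunc(t0, "hours")
      hrs <- seq_len(scenario$duration_hours) - 1L
      pos <- geosphere::destPoint(p0, heading,
                                  scenario$track_speed * 1000 * hrs)
      times <- t0 + hrs * 3600
      storm_starts[[length(storm_starts) + 1L]] <-
        data.frame(year = yr[y], start = t0)
      for (i in seq_len(nrow(sites))) {
        d <- geosphere::distHaversine(pos,
                                      c(sites$lon[i], sites$lat[i])) / 1000
        cw <- vortex_wind(d, scenario$vmax, scenario$rmw, scenario$decay)
        per_site[[i]][[length(per_site[[i]]) + 1L]] <-
          data.frame(timestamp = times, site_id = sites$site_id[i],
                     cyclone_wind = cw,
                     synoptic_wind = stats::rweibull(
                       length(times), scenario$synoptic_shape,
                       scenario$synoptic_scale),
                     distance_to_center = d, eye_radius = scenario$rmw,
                     stringsAsFactors = FALSE)
      }
    }
  }
  series <- lapply(seq_len(nrow(sites)), function(i) {
    if (length(per_site[[i]]) == 0L)
      return(data.frame(timestamp = origin, site_id = sites$site_id[i],
                        cyclone_wind = 0, synoptic_wind = 0,
                        distance_to_center = 1e6,
                        eye_radius = scenario$rmw,
                        stringsAsFactors = FALSE))
    d <- do.call(rbind, per_site[[i]])
    # overlapping storms: keep the stronger cyclone wind per hour
    d <- d[order(d$timestamp, -d$cyclone_wind), , drop = FALSE]
    d <- d[!duplicated(d$timestamp), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(series) <- sites$site_id
  list(series = series, years = yr,
       truth = list(storm_starts = do.call(rbind, storm_starts),
                    storms_per_year = n_storms,
                    scenario = scenario, seed = seed))
}

#' Simulate yearly exposure counts from a Poisson rate
#'
#' Direct Poisson draws of the per-year exposure-event count, for
#' calibration checks of [annual_exposure_probability()].
#'
#' @param lambda True annual exposure rate (events/year).
#' @param years Number of years.
#' @param site_id Site label.
#' @param seed Optional RNG seed.
#' @return An `exposure_series` data frame (`site_id`, `year`, `events`).
#' @export
simulate_exposure_counts <- function(lambda, years, site_id = "site1",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(site_id = site_id,
                    year = seq(1985L, length.out = years),
                    events = stats::rpois(years, lambda),
                    stringsAsFactors = FALSE)
  class(out) <- c("exposure_series", "data.frame")
  out
}

#' Driver-scenario parameters
#'
#' Defines the covariate distributions and the true response surface of a
#' synthetic driver dataset. The default response is hump-shaped in the
#' square root of the cyclone exposure probability (an interior maximum at
#' intermediate disturbance), with optional additive dugong and SST
#' effects; SST is constructed to be strongly collinear with latitude
#' (r >= 0.95) to exercise the collinearity prefilter.
#'
#' @param n_sites Number of sites (default 16).
#' @param lat_range Latitude span, decimal degrees (default 8 degrees in
#'   the southern tropics).
#' @param peak_height Response at the hump peak.
#' @param peak_loc Peak location on the sqrt(cyclone_pr) scale.
#' @param curvature Quadratic fall-off from the peak.
#' @param dugong_effect Additive shift where dugongs are present.
#' @param sst_slope Additive effect per standardized log-SST unit.
#' @param noise_sd Gaussian noise SD on the response (default 0.05).
#' @param dist_shore_cyclone_r Target correlation between distance from
#'   shore and cyclone probability (0 = independent).
#' @return A list of class `driver_scenario`.
#' @export
driver_scenario <- function(n_sites = 16L, lat_range = c(-22.5, -14.5),
                            peak_height = 0.7, peak_loc = 0.55,
                            curvature = 2, dugong_effect = 0,
                            sst_slope = 0, noise_sd = 0.05,
                            dist_shore_cyclone_r = 0) {
  structure(list(n_sites = as.integer(n_sites), lat_range = lat_range,
                 peak_height = peak_height, peak_loc = peak_loc,
                 curvature = curvature, dugong_effect = dugong_effect,
                 sst_slope = sst_slope, noise_sd = noise_sd,
                 dist_shore_cyclone_r = dist_shore_cyclone_r),
            class = "driver_scenario")
}

#' Simulate a site-covariate table with a known response surface
#'
#' Draws site covariates (cyclone exposure probability, dugong
#' presence/absence, SST tied to latitude, turbidity, distance from shore)
#' and generates the clonal-richness response from the scenario's stored
#' function plus Gaussian noise, clipped to \[0, 1\].
#'
#' @param scenario A [driver_scenario()].
#' @param species Species label on the output rows.
#' @param seed Optional RNG seed.
#' @return A list with `covariates` (data frame ready for
#'   [run_driver_analysis()]) and `truth` (`scenario`, the noiseless
#'   response `mu`, and `seed`).
#' @export
simulate_driver_dataset <- function(scenario = driver_scenario(),
                                    species = "synthetic", seed = NULL) {
  stopifnot(inherits(scenario, "driver_scenario"), scenario$n_sites >= 6L)
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_sites
  latitude <- sort(stats::runif(n, scenario$lat_range[1L],
                                scenario$lat_range[2L]))
  # SST tracks latitude closely (warmer toward the equator)
  sst <- 27 + 0.6 * (latitude - mean(latitude)) + stats::rnorm(n, 0, 0.25)
  cyclone_pr <- stats::rbeta(n, 2, 2)
  dugong <- factor(sample(c("present", "absent"), n, replace = TRUE),
                   levels = c("absent", "present"))
  kd490 <- stats::runif(n, 0.02, 0.15)
  if (scenario$dist_shore_cyclone_r != 0) {
    rho <- scenario$dist_shore_cyclone_r
    z <- scale(cyclone_pr)[, 1L]
    e <- stats::rnorm(n)
    mix <- rho * z + sqrt(1 - rho^2) * scale(e)[, 1L]
    dist_shore <- 40 + 18 * mix
    dist_shore <- pmax(dist_shore, 1)
  } else {
    dist_shore <- stats::runif(n, 5, 75)
  }
  mu <- scenario$peak_height -
    scenario$curvature * (sqrt(cyclone_pr) - scenario$peak_loc)^2 +
    scenario$dugong_effect * (dugong == "present") +
    scenario$sst_slope * scale(log(sst))[, 1L]
  R <- pmin(1, pmax(0, mu + stats::rnorm(n, 0, scenario$noise_sd)))
  covariates <- data.frame(
    site_id = sprintf("S%02d", seq_len(n)), species = species,
    latitude = latitude, sst = sst, cyclone_pr = cyclone_pr,
    dugong = dugong, kd490 = kd490, dist_shore = dist_shore, R = R,
    stringsAsFactors = FALSE)
  list(covariates = covariates,
       truth = list(scenario = scenario, mu = mu, seed = seed))
}
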