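# Cyclone exposure: from hourly wind/wave series at a site to yearly
# exposure-event counts and the annual probability of exposure to cyclonic
# seas, Pr(X >= 1) = 1 - exp(-lambda).

#' Blend cyclone and synoptic (background) winds
#'
#' Weighted combination of the cyclone-generated and synoptic wind speeds at
#' a site. Cyclone winds receive full weight within three radii of the
#' cyclone eye (radius of maximum winds); the weight then declines linearly
#' to zero at `outer_multiple` radii, beyond which the synoptic wind is used
#' alone. The result is continuous in distance and bounded between the two
#' input speeds.
#'
#' @param cyclone_wind Cyclone wind speed at the site, m/s.
#' @param synoptic_wind Background synoptic wind speed, m/s.
#' @param distance_to_center Distance from site to cyclone center, km.
#' @param eye_radius Radius of maximum winds, km (> 0 when cyclone winds are
#'   non-zero).
#' @param inner_multiple Full cyclone weight within this many eye radii
#'   (default 3).
#' @param outer_multiple Zero cyclone weight beyond this many eye radii
#'   (default 6).
#' @return Blended wind speed, m/s (vectorized).
#' @examples
#' blend_winds(50, 8, 0, 20)              # 50: at the center
#' blend_winds(50, 8, 90, 20)             # 29: midpoint of the 3->6 ramp
#' blend_winds(50, 8, 200, 20)            # 8: beyond the outer cutoff
#' @export
blend_winds <- function(cyclone_wind, synoptic_wind, distance_to_center,
                        eye_radius, inner_multiple = 3,
                        outer_multiple = 6) {
  if (any(cyclone_wind < 0 | synoptic_wind < 0 | distance_to_center < 0))
    stop("wind speeds and distances must be non-negative")
  if (any(eye_radius <= 0 & cyclone_wind > 0))
    stop("eye_radius must be positive when cyclone wind is non-zero")
  if (outer_multiple <= inner_multiple)
    stop("outer_multiple must exceed inner_multiple")
  r_in <- inner_multiple * eye_radius
  r_out <- outer_multiple * eye_radius
  w <- ifelse(distance_to_center <= r_in, 1,
              ifelse(distance_to_center >= r_out, 0,
                     (r_out - distance_to_center) / (r_out - r_in)))
  w[eye_radius <= 0] <- 0  # no active cyclone
  w * cyclone_wind + (1 - w) * synoptic_wind
}

#' Default wind-to-significant-wave-height map
#'
#' A monotone quadratic map from blended wind speed to significant wave
#' height, calibrated so that the 4 m wave criterion coincides with
#' gale-force blended winds (17.2 m/s): `H_s = h_ref * (w / w_ref)^2`.
#'
#' @param w_ref Reference wind speed, m/s (default gale force, 17.2).
#' @param h_ref Significant wave height at the reference wind, m (default 4).
#' @return A function mapping wind speed (m/s) to H_s (m).
#' @export
default_wave_model <- function(w_ref = 17.2, h_ref = 4) {
  force(w_ref); force(h_ref)
  function(wind) h_ref * (wind / w_ref)^2
}

#' Detect yearly exposure events from an hourly wind/wave series
#'
#' An exposure event is a maximal contiguous run of hours with significant
#' wave height at or above `threshold` lasting at least `min_duration`
#' hours; a 3-day storm is one exposure, not 72. Each event is counted in
#' the year of its first hour. Hours absent from the series (gaps) are
#' treated as below threshold and reported.
#'
#' @param series Data frame for one site with columns `timestamp` (POSIXct,
#'   hourly, sorted, unique), and either `significant_wave_height` (m) or
#'   the wind columns `cyclone_wind`, `synoptic_wind`,
#'   `distance_to_center`, `eye_radius` from which waves are derived via
#'   `wave_model` applied to [blend_winds()].
#' @param threshold Significant wave height criterion, m (default 4).
#' @param min_duration Minimum event length, hours (default 1).
#' @param wave_model Function wind (m/s) -> H_s (m); required when
#'   `significant_wave_height` is absent. See [default_wave_model()].
#' @param years Optional integer vector of years the series is meant to
#'   cover (defaults to the span of the timestamps); years without events
#'   get a zero count.
#' @return A data frame of class `exposure_series` with columns `site_id`,
#'   `year`, `events`; attribute `gap_hours` reports missing hours within
#'   the covered span.
#' @export
exposure_events <- function(series, threshold = 4, min_duration = 1,
                            wave_model = NULL, years = NULL) {
  stopifnot(is.data.frame(series), nrow(series) > 0L,
            "timestamp" %in% names(series))
  ts <- series$timestamp
  if (is.unsorted(ts, strictly = TRUE))
    stop("timestamps must be strictly increasing (sorted, no duplicates)")
  site_id <- if ("site_id" %in% names(series))
    as.character(series$site_id[1L]) else NA_character_
  hs <- series$significant_wave_height
  if (is.null(hs)) {
    if (is.null(wave_model))
      stop("series has no significant_wave_height; supply wave_model")
    hs <- wave_model(blend_winds(series$cyclone_wind, series$synoptic_wind,
                                 series$distance_to_center,
                                 series$eye_radius))
  }
  # gaps (missing hours) count as below threshold
  hours <- as.numeric(difftime(ts, ts[1L], units = "hours"))
  gap_hours <- sum(diff(round(hours)) - 1L)
  contiguous <- c(TRUE, diff(round(hours)) == 1L)
  above <- hs >= threshold
  # break runs at gaps: a run continues only across contiguous hours
  run_id <- cumsum(!above | !contiguous)
  ev_year <- integer(0)
  if (any(above)) {
    runs <- split(seq_along(above)[above], run_id[above])
    for (idx in runs) {
      if (length(idx) >= min_duration)
        ev_year <- c(ev_year, as.integer(format(ts[idx[1L]], "%Y")))
    }
  }
  yr_all <- as.integer(format(ts, "%Y"))
  if (is.null(years)) years <- seq(min(yr_all), max(yr_all))
  counts <- vapply(years, function(y) sum(ev_year == y), integer(1))
  out <- data.frame(site_id = site_id, year = as.integer(years),
                    events = counts, stringsAsFactors = FALSE)
  class(out) <- c("exposure_series", "data.frame")
  attr(out, "gap_hours") <- gap_hours
  if (gap_hours > 0)
    message(gap_hours, " missing hours treated as below threshold")
  out
}

#' Annual probability of exposure to cyclonic seas
#'
#' From yearly exposure-event counts, the Poisson exposure model gives the
#' annual probability of at least one exposure:
#' `Pr(X >= 1) = 1 - exp(-lambda)`, with `lambda` the mean number of
#' exposure events per year.
#'
#' @param series An `exposure_series` (or data frame with columns `site_id`,
#'   `year`, `events`), at least one year.
#' @return A one-row data frame of class `exposure_record` with columns
#'   `site_id`, `lambda` (events/year), `pr_exposed`, `years`,
#'   `total_events`.
#' @examples
#' s <- data.frame(site_id = "S1", year = 2001:2005,
#'                 events = c(1, 0, 2, 1, 0))
#' annual_exposure_probability(s)  # lambda = 0.8, Pr = 1 - exp(-0.8)
#' @export
annual_exposure_probability <- function(series) {
  stopifnot(is.data.frame(series), "events" %in% names(series))
  if (nrow(series) == 0L) stop("empty exposure series")
  if (any(series$events < 0) || any(series$events != round(series$events)))
    stop("event counts must be non-negative integers")
  lambda <- mean(series$events)
  out <- data.frame(
    site_id = if ("site_id" %in% names(series))
      as.character(series$site_id[1L]) else NA_character_,
    lambda = lambda, pr_exposed = 1 - exp(-lambda),
    years = nrow(series), total_events = sum(series$events),
    stringsAsFactors = FALSE)
  class(out) <- c("exposure_record", "data.frame")
  out
}
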