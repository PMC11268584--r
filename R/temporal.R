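#' Hour-of-week activity profile of one user
#'
#' Aggregates a user's events into a 168-bin histogram by hour of week
#' (UTC), bin 1 being Monday 00:00--00:59.
#'
#' @param events Event table for a single user.
#' @return A list of class `"weekly_profile"`: `user_id`, `bins` (integer
#'   vector of length 168 summing to the event count) and `n_events`.
#' @export
weekly_profile <- function(events) {
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) stop_("no events: cannot build a weekly profile")
  if (data.table::uniqueN(events$user_id) > 1L) {
    stop_("weekly_profile() expects events of a single user")
  }
  lt <- as.POSIXlt(events$timestamp, tz = "UTC")
  monday0 <- (lt$wday + 6L) %% 7L  # POSIXlt wday: 0 = Sunday
  idx <- monday0 * 24L + lt$hour + 1L
  structure(list(
    user_id = events$user_id[1L],
    bins = tabulate(idx, nbins = 168L),
    n_events = nrow(events)
  ), class = "weekly_profile")
}

#' Classify the dominant activity period of a weekly profile
#'
#' Computes the discrete Fourier spectrum of the 168-bin hour-of-week
#' profile and compares the power at the three candidate harmonics --- 7,
#' 14 and 28 cycles per week, i.e. periods of 24, 12 and 6 hours. The
#' candidate with maximal power is accepted as the dominant rhythm only if
#' the profile has at least `min_events` events, its power is at least
#' `dominance_ratio` times the next-largest candidate power, and it carries
#' at least `min_power_fraction` of the total non-constant power; otherwise
#' the user is classified as having no detectable rhythm. Ties in candidate
#' power are broken toward the longer period.
#'
#' @param profile A [weekly_profile()], or a plain numeric vector of 168
#'   hour-of-week counts.
#' @param min_events Minimum event count for a classification; default 50.
#' @param dominance_ratio Required ratio of dominant to runner-up candidate
#'   power; default 2.
#' @param min_power_fraction Required fraction of total non-constant power
#'   at the dominant harmonic; default 0.10.
#' @return A list of class `"periodicity_result"`: `user_id`,
#'   `dominant_period_hours` (one of `"24"`, `"12"`, `"6"`, `"none"`),
#'   `candidate_powers` (named, at the 24/12/6-hour harmonics) and
#'   `power_fraction` of the dominant candidate (0 when none).
#' @export
detect_periodicity <- function(profile, min_events = 50,
                               dominance_ratio = 2.0,
                               min_power_fraction = 0.10) {
  if (is.numeric(profile)) {
    profile <- structure(list(user_id = NA_integer_, bins = profile,
                              n_events = sum(profile)),
                         class = "weekly_profile")
  }
  bins <- profile$bins
  if (length(bins) != 168L || any(bins < 0)) {
    stop_("profile bins must be 168 non-negative counts")
  }
  spec <- stats::fft(bins - mean(bins))
  power <- Mod(spec[2:85])^2       # one-sided, harmonics 1..84 cycles/week
  cand <- power[c(7L, 14L, 28L)]
  names(cand) <- c("24", "12", "6")
  total <- sum(power)

  result <- function(dom, frac) {
    structure(list(user_id = profile$user_id, dominant_period_hours = dom,
                   candidate_powers = cand, power_fraction = frac),
              class = "periodicity_result")
  }
  if (total <= .Machine$double.eps * 168 || profile$n_events < min_events) {
    return(result("none", 0))
  }
  ord <- order(-cand)  # stable: ties resolve toward the longer period
  top <- cand[ord[1L]]
  frac <- top / total
  if (top <= 0 ||
      top < dominance_ratio * cand[ord[2L]] ||
      frac < min_power_fraction) {
    return(result("none", 0))
  }
  result(names(cand)[ord[1L]], unname(frac))
}

#' Periodicity census of a user population
#'
#' Tabulates, per user role, the fraction of users whose dominant activity
#' period is 24, 12 or 6 hours, or undetectable.
#'
#' @param results A list of [detect_periodicity()] results, or a
#'   `data.table` with columns `user_id` and `dominant_period_hours`.
#' @param roles A `data.table`/data.frame with columns `user_id` and `role`
#'   (e.g. `"consumer"`, `"producer"`); a user may carry several roles.
#'   When `NULL`, all users are censused under the single role `"all"`.
#' @return A `data.table` with `role`, `period` (`"24"`, `"12"`, `"6"`,
#'   `"none"`), `n` and `fraction`; fractions sum to 1 within each role.
#' @export
periodicity_census <- function(results, roles = NULL) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- data.table::rbindlist(lapply(results, function(r) {
      data.table::data.table(user_id = r$user_id,
                             dominant_period_hours = r$dominant_period_hours)
    }))
  }
  results <- data.table::as.data.table(results)
  if (nrow(results) == 0L) stop_("no periodicity results to census")
  if (is.null(roles)) {
    roles <- data.table::data.table(user_id = results$user_id, role = "all")
  }
  roles <- data.table::as.data.table(roles)
  joined <- results[roles, on = "user_id", nomatch = NULL]
  if (nrow(joined) == 0L) stop_("roles do not match any classified user")
  levels <- c("24", "12", "6", "none")
  out <- joined[, {
    n <- vapply(levels, function(l) sum(dominant_period_hours == l), integer(1))
    .(period = levels, n = n, fraction = n / sum(n))
  }, by = role]
  out[]
}

#' Weekly profiles and periodicity for every user of a log
#'
#' Convenience wrapper running [weekly_profile()] and
#' [detect_periodicity()] per user.
#'
#' @param events Multi-user event table.
#' @inheritParams detect_periodicity
#' @return A `data.table` with `user_id`, `n_events`,
#'   `dominant_period_hours` and `power_fraction`.
#' @export
classify_periodicities <- function(events, min_events = 50,
                                   dominance_ratio = 2.0,
                                   min_power_fraction = 0.10) {
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) stop_("no events")
  events[, {
    prof <- weekly_profile(data.table::data.table(user_id = .BY$user_id,
                                                  timestamp = timestamp))
    r <- detect_periodicity(prof, min_events, dominance_ratio,
                            min_power_fraction)
    .(n_events = .N, dominant_period_hours = r$dominant_period_hours,
      power_fraction = r$power_fraction)
  }, by = user_id][]
}
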