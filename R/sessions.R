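#' Segment one user's events into sessions
#'
#' A session is a maximal run of one user's events in which every gap
#' between consecutive events is below the inactivity threshold. A gap
#' greater than or equal to `gap_threshold` minutes ("inactive for an hour
#' or more" at the 60-minute default) starts a new session.
#'
#' @param events Event table for a single user, sorted by timestamp.
#' @param gap_threshold Inactivity threshold in minutes (> 0); default 60.
#' @param event_types Which event types to include; defaults to pooling
#'   views and posts.
#' @return A `data.table` with one row per session: `user_id`, `session_id`
#'   (1-based, chronological), `start`, `end`, `n_events` and `duration_min`
#'   (`end - start`; 0 for single-event sessions).
#' @seealso [sessionize()] for a whole multi-user log,
#'   [session_duration_stats()].
#' @export
segment_sessions <- function(events, gap_threshold = 60,
                             event_types = c("view", "post")) {
  events <- data.table::as.data.table(events)
  if (gap_threshold <= 0) stop_("gap_threshold must be > 0")
  events <- events[event_type %in% event_types]
  if (nrow(events) == 0L) {
    return(data.table::data.table(
      user_id = integer(), session_id = integer(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"),
      n_events = integer(), duration_min = numeric()
    ))
  }
  if (data.table::uniqueN(events$user_id) > 1L) {
    stop_("segment_sessions() expects events of a single user; ",
          "use sessionize() for a full log")
  }
  ts <- as.numeric(events$timestamp)
  if (is.unsorted(ts)) stop_("events must be sorted by timestamp")
  gap_min <- diff(ts) / 60
  session_id <- cumsum(c(1L, as.integer(gap_min >= gap_threshold)))
  events[, .(
    start = timestamp[1L], end = timestamp[.N], n_events = .N,
    duration_min = as.numeric(difftime(timestamp[.N], timestamp[1L],
                                       units = "mins"))
  ), by = .(user_id, session_id = session_id)][]
}

#' Segment a whole event log into sessions
#'
#' Applies [segment_sessions()] to every user of a multi-user log.
#'
#' @inheritParams segment_sessions
#' @param events Event table (any number of users), sorted by
#'   `(user_id, timestamp)`.
#' @return A `data.table` of sessions for all users (see
#'   [segment_sessions()]); `session_id` is per-user.
#' @export
sessionize <- function(events, gap_threshold = 60,
                       event_types = c("view", "post")) {
  events <- data.table::as.data.table(events)
  events <- events[event_type %in% event_types]
  if (nrow(events) == 0L) stop_("no events to segment")
  events[, {
    ts <- as.numeric(timestamp)
    if (is.unsorted(ts)) stop_("events must be sorted by timestamp ",
                               "within user ", user_id[1L])
    sid <- cumsum(c(1L, as.integer(diff(ts) / 60 >= gap_threshold)))
    .SD[, .(start = timestamp[1L], end = timestamp[.N], n_events = .N,
            duration_min = as.numeric(difftime(timestamp[.N], timestamp[1L],
                                               units = "mins"))),
        by = .(session_id = sid)]
  }, by = user_id][]
}

#' Inter-event times of one user's stream
#'
#' @param events Event table for a single user, sorted by timestamp.
#' @return Numeric vector of the `n - 1` consecutive gaps in minutes
#'   (empty for fewer than two events).
#' @export
interevent_times <- function(events) {
  events <- data.table::as.data.table(events)
  if (nrow(events) && data.table::uniqueN(events$user_id) > 1L) {
    stop_("interevent_times() expects events of a single user")
  }
  ts <- as.numeric(events$timestamp)
  if (is.unsorted(ts)) stop_("events must be sorted by timestamp")
  if (length(ts) < 2L) return(numeric())
  diff(ts) / 60
}

#' Log-binned histogram of inter-event times
#'
#' Bins gaps into base-10 logarithmic bins spanning 1 minute to 60 days
#' (the time scale over which forum inter-event times range); gaps under a
#' minute fall into the first bin.
#'
#' @param gaps_min Numeric vector of gaps in minutes.
#' @param bins_per_decade Number of bins per factor of 10; default 4.
#' @return A `data.table` with `lower`, `upper` (minutes) and `count`.
#' @export
interevent_histogram <- function(gaps_min, bins_per_decade = 4) {
  if (length(gaps_min) == 0L) stop_("no gaps to bin")
  if (any(gaps_min < 0)) stop_("gaps must be non-negative")
  upper_max <- 60 * 24 * 60  # 60 days in minutes
  edges <- 10^seq(0, ceiling(log10(upper_max) * bins_per_decade) / bins_per_decade,
                  by = 1 / bins_per_decade)
  edges <- c(0, edges)
  idx <- findInterval(gaps_min, edges, rightmost.closed = TRUE)
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  data.table::data.table(
    lower = edges[-length(edges)],
    upper = edges[-1L],
    count = tabulate(idx, nbins = length(edges) - 1L)
  )
}

#' Session duration statistics
#'
#' Mean session duration and the survival fraction of sessions lasting at
#' least each probe duration; all sessions, including zero-duration
#' single-event sessions, enter the statistics. Optionally attaches a
#' log-binned histogram of raw inter-event gaps.
#'
#' @param sessions Session table from [segment_sessions()] or
#'   [sessionize()].
#' @param probe_points Durations (minutes) at which to evaluate the
#'   survival function; default `c(10, 60)`.
#' @param interevent_minutes Optional vector of raw inter-event gaps
#'   (minutes) to histogram alongside.
#' @return A list of class `"session_stats"`: `n_sessions`,
#'   `mean_duration` (minutes), `survival_at` (named fractions), and
#'   `interevent_histogram` (or `NULL`).
#' @export
session_duration_stats <- function(sessions, probe_points = c(10, 60),
                                   interevent_minutes = NULL) {
  sessions <- data.table::as.data.table(sessions)
  if (nrow(sessions) == 0L) stop_("no sessions: nothing to summarise")
  dur <- sessions$duration_min
  surv <- vapply(probe_points, function(p) mean(dur >= p), numeric(1))
  structure(list(
    n_sessions = nrow(sessions),
    mean_duration = mean(dur),
    survival_at = stats::setNames(surv, probe_points),
    interevent_histogram = if (!is.null(interevent_minutes)) {
      interevent_histogram(interevent_minutes)
    }
  ), class = "session_stats")
}

#' @export
print.session_stats <- function(x, ...) {
  cat(sprintf("Session statistics over %d sessions\n", x$n_sessions))
  cat(sprintf("  mean duration: %.1f min\n", x$mean_duration))
  for (p in names(x$survival_at)) {
    cat(sprintf("  P(duration >= %s min) = %.3f\n", p, x$survival_at[[p]]))
  }
  invisible(x)
}
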