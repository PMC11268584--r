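# shared fixtures and metrics for the test suite

# event table built from minute offsets relative to a fixed Monday origin
monday_origin <- as.POSIXct("2014-01-06 00:00:00", tz = "UTC")

events_at_minutes <- function(minutes, user_id = 1L, category_id = 1L,
                              event_type = "view", origin = monday_origin) {
  n <- length(minutes)
  data.table::data.table(
    event_id = seq_len(n),
    user_id = rep_len(as.integer(user_id), n),
    post_id = rep_len(1L, n),
    category_id = rep_len(as.integer(category_id), n),
    event_type = rep_len(event_type, n),
    timestamp = origin + round(minutes * 60)
  )
}

# random multi-user event log for property tests
random_event_log <- function(n_events, n_users = 5L, n_categories = 4L,
                             span_min = 3000) {
  data.table::data.table(
    event_id = seq_len(n_events),
    user_id = sample.int(n_users, n_events, replace = TRUE),
    post_id = sample.int(100L, n_events, replace = TRUE),
    category_id = sample.int(n_categories, n_events, replace = TRUE),
    event_type = sample(c("view", "post"), n_events, replace = TRUE,
                        prob = c(0.9, 0.1)),
    timestamp = monday_origin + sort(sample.int(span_min * 60, n_events))
  )[order(user_id, timestamp)]
}

# adjusted Rand index: label-permutation-invariant agreement of two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force periodogram power at a given cycles-per-week harmonic,
# independent of the fft-based implementation path
periodogram_power <- function(bins, cycles_per_week) {
  x <- bins - mean(bins)
  h <- seq_along(bins) - 1L
  re <- sum(x * cos(2 * pi * cycles_per_week * h / length(bins)))
  im <- sum(x * sin(2 * pi * cycles_per_week * h / length(bins)))
  re^2 + im^2
}
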