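#' Configuration for the synthetic forum-log generator
#'
#' Builds the parameter set for [generate_population()] and
#' [generate_events()]. The defaults define the generator's reference
#' conditions: 500 users over 8 weeks, 67 categories (half in the Sexual
#' COPINE segment), 8 preference archetypes of which 3 are narrow, bursty
#' within-session timing whose session statistics match the behavioural
#' regularities the pipeline is designed to detect (mean session duration
#' about 40 minutes, about 85\% of sessions lasting at least 10 minutes and
#' about 25\% at least an hour, a mean of about 20 distinct categories viewed
#' per user, and about 10 posts per producer).
#'
#' Preference model: every user devotes a fixed `core_overlap` share of
#' attention to a sexual "core" common to all archetypes (weights drawn from
#' a tight symmetric Dirichlet with precision `core_concentration`), and the
#' remaining share to the archetype's own block of NonSexual categories,
#' with weights drawn from a symmetric Dirichlet whose precision is that
#' archetype's entry of `archetype_concentrations`. Low concentration gives
#' narrow, idiosyncratic within-block preferences; high concentration gives
#' broad, even ones.
#'
#' Session model: per user, session start times follow a renewal process
#' thinned by `1 + rhythm_amplitude * cos(2*pi*t/period + phase)` for users
#' with an assigned rhythm; each session has `min_events` plus a geometric
#' number of extra events, with within-session gaps drawn from a lognormal
#' (minutes) truncated strictly below the 60-minute session threshold, and
#' consecutive sessions separated by strictly more than 60 minutes by
#' construction, so the segmentation stage has an exact ground truth.
#'
#' @param n_users Number of users.
#' @param n_categories Number of content categories.
#' @param n_archetypes Number of preference archetypes.
#' @param archetype_concentrations Dirichlet precision per archetype for
#'   within-block preference weights (low = narrow). Defaults to 3 narrow
#'   archetypes (15) and the rest broad (80).
#' @param sexual_fraction Fraction of categories with COPINE grade >= 7.
#' @param core_overlap Share of every user's attention spent on the shared
#'   Sexual core.
#' @param core_concentration Dirichlet precision of the shared core weights.
#' @param activity_law `c(meanlog=, sdlog=)` of the lognormal law for target
#'   view counts per user (heavy-tailed activity).
#' @param posts_per_user_mean Expected number of post events per producer.
#' @param producer_fraction Fraction of users who also post.
#' @param period_mix Named fractions of users assigned an activity rhythm of
#'   period 24, 12 or 6 hours, or none; must sum to 1.
#' @param rhythm_amplitude Relative modulation depth of session-start rates
#'   for rhythmic users, in `[0, 1)`.
#' @param session_gap_mean_hours Lower bound on a user's mean inter-session
#'   spacing (hours, > 1); pacing otherwise spreads each user's sessions
#'   across the time window.
#' @param within_session_gap_law `c(meanlog=, sdlog=)` of the lognormal law
#'   (minutes) for within-session inter-event gaps, truncated below 60.
#' @param events_per_session_law `c(min_events=, prob=)`: events per session
#'   are `min_events + rgeom(prob)`.
#' @param time_window Length-2 `POSIXct` (UTC): start and end of the
#'   simulated observation window.
#' @param seed Default seed used by the generator functions.
#' @return A list of class `"forum_config"`.
#' @export
forum_config <- function(n_users = 500L,
                         n_categories = 67L,
                         n_archetypes = 8L,
                         archetype_concentrations = NULL,
                         sexual_fraction = 0.5,
                         core_overlap = 0.3,
                         core_concentration = 500,
                         activity_law = c(meanlog = 4.2, sdlog = 1.1),
                         posts_per_user_mean = 10,
                         producer_fraction = 0.2,
                         period_mix = c("24" = 0.5, "12" = 0.2, "6" = 0.1, none = 0.2),
                         rhythm_amplitude = 0.8,
                         session_gap_mean_hours = 2,
                         within_session_gap_law = c(meanlog = 1.1, sdlog = 0.9),
                         events_per_session_law = c(min_events = 3, prob = 0.12),
                         time_window = as.POSIXct(c("2014-01-06 00:00:00",
                                                    "2014-03-03 00:00:00"),
                                                  tz = "UTC"),
                         seed = 42L) {
  if (is.null(archetype_concentrations)) {
    n_narrow <- max(1L, round(3 / 8 * n_archetypes))
    archetype_concentrations <- c(rep(15, n_narrow),
                                  rep(80, n_archetypes - n_narrow))
  }
  cfg <- structure(list(
    n_users = as.integer(n_users),
    n_categories = as.integer(n_categories),
    n_archetypes = as.integer(n_archetypes),
    archetype_concentrations = archetype_concentrations,
    sexual_fraction = sexual_fraction,
    core_overlap = core_overlap,
    core_concentration = core_concentration,
    activity_law = activity_law,
    posts_per_user_mean = posts_per_user_mean,
    producer_fraction = producer_fraction,
    period_mix = period_mix,
    rhythm_amplitude = rhythm_amplitude,
    session_gap_mean_hours = session_gap_mean_hours,
    within_session_gap_law = within_session_gap_law,
    events_per_session_law = events_per_session_law,
    time_window = time_window,
    seed = as.integer(seed)
  ), class = "forum_config")
  validate_forum_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every field of a [forum_config()]; the error message names the
#' offending field.
#'
#' @param config A `forum_config` list.
#' @return `config`, invisibly, if valid.
#' @export
validate_forum_config <- function(config) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop_("invalid config field ", sQuote(field), ": ", why)
  }
  chk(config$n_users >= 1L, "n_users", "must be >= 1")
  chk(config$n_categories >= 2L, "n_categories", "must be >= 2")
  chk(config$n_archetypes >= 1L, "n_archetypes", "must be >= 1")
  chk(length(config$archetype_concentrations) == config$n_archetypes,
      "archetype_concentrations", "length must equal n_archetypes")
  chk(all(config$archetype_concentrations > 0),
      "archetype_concentrations", "must be strictly positive")
  chk(config$sexual_fraction > 0 && config$sexual_fraction < 1,
      "sexual_fraction", "must be in (0, 1)")
  chk(config$core_overlap >= 0 && config$core_overlap < 1,
      "core_overlap", "must be in [0, 1)")
  chk(config$core_concentration > 0, "core_concentration", "must be > 0")
  chk(all(c("meanlog", "sdlog") %in% names(config$activity_law)) &&
        config$activity_law[["sdlog"]] > 0,
      "activity_law", "needs meanlog and sdlog > 0")
  chk(config$posts_per_user_mean >= 1, "posts_per_user_mean", "must be >= 1")
  chk(config$producer_fraction >= 0 && config$producer_fraction <= 1,
      "producer_fraction", "must be in [0, 1]")
  chk(setequal(names(config$period_mix), c("24", "12", "6", "none")) &&
        abs(sum(config$period_mix) - 1) < 1e-8 && all(config$period_mix >= 0),
      "period_mix", "fractions over {24, 12, 6, none} must be >= 0 and sum to 1")
  chk(config$rhythm_amplitude >= 0 && config$rhythm_amplitude < 1,
      "rhythm_amplitude", "must be in [0, 1)")
  chk(config$session_gap_mean_hours > 1,
      "session_gap_mean_hours", "must exceed 1 hour")
  gl <- config$within_session_gap_law
  chk(all(c("meanlog", "sdlog") %in% names(gl)) && gl[["sdlog"]] > 0,
      "within_session_gap_law", "needs meanlog and sdlog > 0")
  mean_gap <- mean(rlnorm_trunc_mean(gl[["meanlog"]], gl[["sdlog"]], 59.9))
  chk(mean_gap < 60, "within_session_gap_law",
      "mean within-session gap must be < 60 minutes")
  el <- config$events_per_session_law
  chk(all(c("min_events", "prob") %in% names(el)) && el[["min_events"]] >= 1 &&
        el[["prob"]] > 0 && el[["prob"]] <= 1,
      "events_per_session_law", "needs min_events >= 1 and prob in (0, 1]")
  chk(length(config$time_window) == 2L &&
        inherits(config$time_window, "POSIXct") &&
        diff(as.numeric(config$time_window)) > 0,
      "time_window", "must be two increasing POSIXct instants")
  invisible(config)
}

# mean of lognormal truncated above at `upper` (closed form)
rlnorm_trunc_mean <- function(meanlog, sdlog, upper) {
  z <- (log(upper) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * stats::pnorm(z - sdlog) / stats::pnorm(z)
}

#' Generate the category table for a synthetic forum
#'
#' The last `ceiling(sexual_fraction * n_categories)` category ids form the
#' Sexual segment (COPINE grades 7--10); the rest are NonSexual (grades
#' 1--6). Grades within a segment are assigned at random.
#'
#' @param config A [forum_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `data.table` with `category_id`, `label`, `copine_grade`,
#'   `segment`.
#' @export
generate_categories <- function(config = forum_config(), seed = config$seed) {
  validate_forum_config(config)
  set.seed(seed)
  n <- config$n_categories
  n_sex <- ceiling(config$sexual_fraction * n)
  grade <- c(sample(1:6, n - n_sex, replace = TRUE),
             sample(7:10, n_sex, replace = TRUE))
  data.table::data.table(
    category_id = seq_len(n),
    label = sprintf("cat_%02d", seq_len(n)),
    copine_grade = as.integer(grade),
    segment = copine_segment(grade)
  )
}

#' Generate a synthetic user population
#'
#' Samples, for each user: an archetype (uniform mixture), category
#' preference weights from the archetype's core-plus-block Dirichlet model,
#' an activity rhythm period per `period_mix` with a uniform phase, a target
#' view count from the heavy-tailed activity law, and (for the producer
#' subset) a target post count `1 + Poisson(posts_per_user_mean - 1)`.
#'
#' @param config A [forum_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `"forum_population"` with elements
#'   `users` (a `data.table`: `user_id`, `archetype`, `rhythm_period` in
#'   `{"24","12","6","none"}`, `rhythm_phase`, `target_views`,
#'   `target_posts`), `category_weights` (an `n_users x n_categories`
#'   matrix of per-user preference weights, rows summing to 1), and
#'   `archetype_blocks` (the NonSexual category block of each archetype).
#' @export
generate_population <- function(config = forum_config(), seed = config$seed) {
  validate_forum_config(config)
  set.seed(seed)
  n <- config$n_users
  n_cat <- config$n_categories
  n_sex <- ceiling(config$sexual_fraction * n_cat)
  sex_cats <- (n_cat - n_sex + 1L):n_cat
  nonsex_cats <- seq_len(n_cat - n_sex)

  # near-equal contiguous blocks of NonSexual categories, one per archetype
  cuts <- round(seq(0, length(nonsex_cats), length.out = config$n_archetypes + 1L))
  blocks <- lapply(seq_len(config$n_archetypes),
                   function(a) nonsex_cats[(cuts[a] + 1L):cuts[a + 1L]])

  archetype <- sample.int(config$n_archetypes, n, replace = TRUE)
  periods <- sample(names(config$period_mix), n, replace = TRUE,
                    prob = config$period_mix)
  phase <- stats::runif(n, 0, 2 * pi)
  target_views <- pmax(1L, as.integer(round(stats::rlnorm(
    n, config$activity_law[["meanlog"]], config$activity_law[["sdlog"]]))))
  producer <- stats::runif(n) < config$producer_fraction
  target_posts <- integer(n)
  target_posts[producer] <- 1L + stats::rpois(sum(producer),
                                              config$posts_per_user_mean - 1)

  co <- config$core_overlap
  weights <- matrix(0, n, n_cat)
  for (i in seq_len(n)) {
    a <- archetype[i]
    if (co > 0) {
      weights[i, sex_cats] <-
        co * rdirichlet(rep(config$core_concentration / n_sex, n_sex))
    }
    b <- blocks[[a]]
    weights[i, b] <- (1 - co) *
      rdirichlet(rep(config$archetype_concentrations[a] / length(b), length(b)))
  }

  structure(list(
    users = data.table::data.table(
      user_id = seq_len(n), archetype = archetype, rhythm_period = periods,
      rhythm_phase = phase, target_views = target_views,
      target_posts = target_posts
    ),
    category_weights = weights,
    archetype_blocks = blocks
  ), class = "forum_population")
}

#' Generate a synthetic event log
#'
#' Simulates every user's event stream over the configured time window:
#' session start times from a thinned renewal process (rate modulated by the
#' user's rhythm, if any), a shifted-geometric number of events per session,
#' bursty within-session gaps (truncated lognormal, always under 60
#' minutes), consecutive sessions always separated by more than 60 minutes,
#' categories sampled from the user's preference weights, and post events
#' interleaved at random positions for producers.
#'
#' @param population A [generate_population()] result.
#' @param config The [forum_config()] used to build the population.
#' @param seed Integer seed (defaults to `config$seed + 1` so that
#'   population and event randomness are decoupled).
#' @return A list of class `"forum_events"`: `events` (an event
#'   `data.table` in [read_event_log()] layout, sorted by user and time) and
#'   `truth` (ground-truth labels the analysis pipeline never reads:
#'   per-user `archetype`, `rhythm_period`, `rhythm_phase`, `n_sessions`,
#'   `n_views`, `n_posts`, plus `total_sessions`).
#' @export
generate_events <- function(population, config = forum_config(),
                            seed = config$seed + 1L) {
  if (!inherits(population, "forum_population")) {
    stop_("population must be created by generate_population()")
  }
  if (nrow(population$users) == 0L) stop_("empty population")
  validate_forum_config(config)
  set.seed(seed)

  window_h <- as.numeric(difftime(config$time_window[2L],
                                  config$time_window[1L], units = "hours"))
  gl <- config$within_session_gap_law
  el <- config$events_per_session_law
  n_min <- as.integer(el[["min_events"]])
  p_geo <- el[["prob"]]
  mean_sess_events <- n_min + (1 - p_geo) / p_geo
  sess_len_h <- (mean_sess_events - 1) *
    rlnorm_trunc_mean(gl[["meanlog"]], gl[["sdlog"]], 59.9) / 60
  gap_floor_h <- 61.2 / 60  # strictly > 1 h even after second rounding

  users <- population$users
  res_user <- vector("list", nrow(users))
  truth_sessions <- integer(nrow(users))
  post_id_next <- 1000000L

  for (i in seq_len(nrow(users))) {
    u <- users[i]
    total_events <- u$target_views + u$target_posts
    s_target <- max(1L, ceiling(total_events / mean_sess_events))
    # spread this user's sessions across the window; the configured mean gap
    # acts as a floor so sessions are never packed tighter than it
    nominal_gap_h <- max(config$session_gap_mean_hours,
                         window_h / (s_target + 1))
    amp <- if (u$rhythm_period == "none") 0 else config$rhythm_amplitude
    period_h <- if (u$rhythm_period == "none") Inf
                else as.numeric(u$rhythm_period)
    g_eff <- max(0.02, (nominal_gap_h - sess_len_h - gap_floor_h) / (1 + amp))

    t_h <- 0
    ev_times <- vector("list", s_target + 8L)
    n_sessions <- 0L
    n_done <- 0L
    while (n_done < total_events) {
      # next session start: renewal + thinning against the rhythm profile
      t_h <- t_h + gap_floor_h
      repeat {
        t_h <- t_h + stats::rexp(1L, 1 / g_eff)
        if (t_h >= window_h) break
        if (amp == 0) break
        if (stats::runif(1L) <
            (1 + amp * cos(2 * pi * t_h / period_h + u$rhythm_phase)) /
            (1 + amp)) break
      }
      if (t_h >= window_h) break
      n_ev <- n_min + stats::rgeom(1L, p_geo)
      gaps_min <- rlnorm_trunc(n_ev - 1L, gl[["meanlog"]], gl[["sdlog"]], 59.9)
      times <- t_h + cumsum(c(0, gaps_min)) / 60
      if (times[n_ev] > window_h) break  # whole session must fit the window
      n_sessions <- n_sessions + 1L
      ev_times[[n_sessions]] <- times
      t_h <- times[n_ev]
      n_done <- n_done + n_ev
    }
    if (n_sessions == 0L) {
      # window exhausted before the first accepted start: place one minimal
      # session at a uniform time so every user appears in the log
      t0 <- stats::runif(1L, 0, max(1, window_h - n_min))
      gaps_min <- rlnorm_trunc(n_min - 1L, gl[["meanlog"]], gl[["sdlog"]], 59.9)
      ev_times[[1L]] <- t0 + cumsum(c(0, gaps_min)) / 60
      n_sessions <- 1L
    }
    times_h <- unlist(ev_times[seq_len(n_sessions)], use.names = FALSE)
    n_total <- length(times_h)
    truth_sessions[i] <- n_sessions

    cats <- sample.int(config$n_categories, n_total, replace = TRUE,
                       prob = population$category_weights[i, ])
    type <- rep("view", n_total)
    n_posts_u <- min(u$target_posts, n_total)
    if (n_posts_u > 0L) {
      type[sample.int(n_total, n_posts_u)] <- "post"
    }
    pid <- cats * 1000L + sample.int(50L, n_total, replace = TRUE)
    is_post <- type == "post"
    if (any(is_post)) {
      pid[is_post] <- post_id_next + seq_len(sum(is_post)) - 1L
      post_id_next <- post_id_next + sum(is_post)
    }
    res_user[[i]] <- data.table::data.table(
      user_id = u$user_id, post_id = pid, category_id = cats,
      event_type = type,
      timestamp = config$time_window[1L] + round(times_h * 3600)
    )
  }

  events <- data.table::rbindlist(res_user)
  data.table::setorder(events, user_id, timestamp)
  events[, event_id := seq_len(.N)]
  data.table::setcolorder(events, c("event_id", "user_id", "post_id",
                                    "category_id", "event_type", "timestamp"))

  truth <- list(
    users = data.table::data.table(
      user_id = users$user_id, archetype = users$archetype,
      rhythm_period = users$rhythm_period, rhythm_phase = users$rhythm_phase,
      n_sessions = truth_sessions,
      n_views = events[, sum(event_type == "view"), by = user_id]$V1,
      n_posts = events[, sum(event_type == "post"), by = user_id]$V1
    ),
    total_sessions = sum(truth_sessions)
  )
  structure(list(events = events, truth = truth), class = "forum_events")
}

#' Simulate a complete synthetic forum
#'
#' Convenience wrapper: categories, population and events from one config
#' and seed.
#'
#' @param config A [forum_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `categories`, `population`, `events` (event table)
#'   and `truth`.
#' @export
simulate_forum <- function(config = forum_config(), seed = config$seed) {
  categories <- generate_categories(config, seed)
  population <- generate_population(config, seed)
  gen <- generate_events(population, config, seed + 1L)
  list(categories = categories, population = population,
       events = gen$events, truth = gen$truth)
}
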