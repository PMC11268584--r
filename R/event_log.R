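#' Read a forum event log
#'
#' Reads a timestamped event log in which each row records one user
#' interaction (a view or a post) with a piece of content in a category.
#' Timestamps must be ISO 8601 in UTC with an explicit `Z` suffix
#' (e.g. `2014-02-01T10:00:00Z`); rows without an explicit UTC marker are
#' rejected rather than silently localised.
#'
#' @param path Path to a CSV file with header
#'   `event_id,user_id,post_id,category_id,event_type,timestamp`.
#' @return A [data.table::data.table] with one row per event, sorted by
#'   `(user_id, timestamp)` with file order preserved for ties, and columns
#'   `event_id`, `user_id`, `post_id`, `category_id` (integer),
#'   `event_type` (`"view"` or `"post"`) and `timestamp` (`POSIXct`, UTC).
#' @seealso [write_event_log()], [read_categories()]
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop_("event log file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    integer = c("event_id", "user_id", "post_id", "category_id"),
    character = c("event_type", "timestamp")
  ), na.strings = NULL)
  required <- c("event_id", "user_id", "post_id", "category_id",
                "event_type", "timestamp")
  if (!identical(names(dt)[seq_along(required)], required)) {
    stop_("event log header must be: ", paste(required, collapse = ","))
  }
  if (nrow(dt) == 0L) {
    dt[, timestamp := as.POSIXct(character(), tz = "UTC")]
    return(dt[])
  }
  bad_type <- which(!dt$event_type %in% c("view", "post"))
  if (length(bad_type)) {
    stop_("unknown event_type ", sQuote(dt$event_type[bad_type[1L]]),
          " at line ", bad_type[1L] + 1L)  # +1 for the header line
  }
  ts_ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", dt$timestamp)
  if (!all(ts_ok)) {
    bad <- which(!ts_ok)[1L]
    stop_("malformed or non-UTC timestamp ", sQuote(dt$timestamp[bad]),
          " at line ", bad + 1L, " (expected e.g. 2014-02-01T10:00:00Z)")
  }
  ids <- c("event_id", "user_id", "post_id", "category_id")
  for (col in ids) {
    v <- dt[[col]]
    if (anyNA(v) || any(v < 0L)) {
      bad <- which(is.na(v) | v < 0L)[1L]
      stop_("malformed ", col, " at line ", bad + 1L)
    }
  }
  dt[, timestamp := as.POSIXct(sub("Z$", "", timestamp),
                               format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  if (anyNA(dt$timestamp)) {
    stop_("unparseable timestamp at line ", which(is.na(dt$timestamp))[1L] + 1L)
  }
  data.table::setorder(dt, user_id, timestamp)  # radix sort, stable for ties
  dt[]
}

#' Write a forum event log
#'
#' Inverse of [read_event_log()]: writes events as CSV with ISO 8601 UTC
#' timestamps, so that a write/read round trip reproduces every field.
#'
#' @param events Event table as returned by [read_event_log()] or
#'   [generate_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  out <- data.table::as.data.table(events)[, .(
    event_id, user_id, post_id, category_id, event_type,
    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a category table with COPINE grades
#'
#' Each content category carries a severity grade on the 10-level COPINE
#' scale. Categories graded 6 or below form the `"NonSexual"` segment;
#' grades 7 to 10 form the `"Sexual"` segment.
#'
#' @param path Path to a CSV file with header `category_id,label,copine_grade`.
#' @return A `data.table` with columns `category_id`, `label`,
#'   `copine_grade` and the derived `segment`.
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) stop_("category file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(
    integer = c("category_id", "copine_grade"), character = "label"
  ), na.strings = NULL)
  required <- c("category_id", "label", "copine_grade")
  if (!identical(names(dt)[seq_along(required)], required)) {
    stop_("category header must be: ", paste(required, collapse = ","))
  }
  if (nrow(dt) && (anyNA(dt$copine_grade) ||
                   any(dt$copine_grade < 1L | dt$copine_grade > 10L))) {
    bad <- which(is.na(dt$copine_grade) |
                   dt$copine_grade < 1L | dt$copine_grade > 10L)[1L]
    stop_("copine_grade outside 1..10 at line ", bad + 1L)
  }
  dt[, segment := copine_segment(copine_grade)]
  dt[]
}

#' COPINE segment of a grade
#'
#' Maps COPINE grades to the two-way severity segmentation used throughout
#' the package: grades 1--6 are `"NonSexual"`, grades 7--10 `"Sexual"`.
#'
#' @param grade Integer vector of COPINE grades in 1..10.
#' @return Character vector, `"NonSexual"` or `"Sexual"`.
#' @export
copine_segment <- function(grade) {
  if (any(is.na(grade) | grade < 1 | grade > 10)) {
    stop_("copine grade must be in 1..10")
  }
  ifelse(grade <= 6, "NonSexual", "Sexual")
}

#' Write a category table
#'
#' @param categories Category table (as from [read_categories()] or
#'   [generate_categories()]); the derived `segment` column is not written.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_categories <- function(categories, path) {
  out <- data.table::as.data.table(categories)[, .(category_id, label, copine_grade)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Descriptive summary of an event log
#'
#' Computes the basic activity descriptives of a forum log: overall counts,
#' per-user view/post distributions, per-user unique-category counts, and
#' cumulative daily time series of views and posts (UTC calendar days; days
#' with no activity carry the previous cumulative value).
#'
#' @param events Event table (see [read_event_log()]).
#' @return A list of class `"descriptive_summary"` with elements
#'   `n_users`, `n_posts`, `n_views`, `n_categories`,
#'   `views_per_user`, `posts_per_user`,
#'   `unique_categories_viewed_per_user`, `unique_categories_posted_per_user`
#'   (named integer vectors, names are user ids), and
#'   `cumulative_daily_views`, `cumulative_daily_posts`
#'   (`data.table`s with columns `date`, `count`, `cumulative`).
#' @export
descriptive_summary <- function(events) {
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) stop_("empty event log: nothing to summarise")

  views <- events[event_type == "view"]
  posts <- events[event_type == "post"]

  per_user_tab <- function(dt, fun) {
    x <- dt[, .(v = fun(.SD)), by = user_id, .SDcols = "category_id"]
    stats::setNames(as.integer(x$v), x$user_id)
  }
  daily_cum <- function(dt) {
    if (nrow(dt) == 0L) {
      return(data.table::data.table(date = as.Date(character()),
                                    count = integer(), cumulative = integer()))
    }
    d <- dt[, .(count = .N), by = .(date = as.Date(timestamp, tz = "UTC"))]
    data.table::setorder(d, date)
    full <- data.table::data.table(date = seq(min(d$date), max(d$date), by = "day"))
    d <- d[full, on = "date"]
    d[is.na(count), count := 0L]
    d[, cumulative := cumsum(count)]
    d[]
  }

  structure(list(
    n_users = data.table::uniqueN(events$user_id),
    n_posts = nrow(posts),
    n_views = nrow(views),
    n_categories = data.table::uniqueN(events$category_id),
    views_per_user = per_user_tab(views, nrow),
    posts_per_user = per_user_tab(posts, nrow),
    unique_categories_viewed_per_user =
      per_user_tab(views, function(sd) data.table::uniqueN(sd$category_id)),
    unique_categories_posted_per_user =
      per_user_tab(posts, function(sd) data.table::uniqueN(sd$category_id)),
    cumulative_daily_views = daily_cum(views),
    cumulative_daily_posts = daily_cum(posts)
  ), class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat("Forum event log summary\n")
  cat(sprintf("  users: %d   categories: %d\n", x$n_users, x$n_categories))
  cat(sprintf("  views: %d   posts: %d\n", x$n_views, x$n_posts))
  if (length(x$views_per_user)) {
    cat(sprintf("  views/user: median %.0f, mean %.1f\n",
                stats::median(x$views_per_user), mean(x$views_per_user)))
  }
  if (length(x$unique_categories_viewed_per_user)) {
    cat(sprintf("  distinct categories viewed/user: mean %.1f\n",
                mean(x$unique_categories_viewed_per_user)))
  }
  invisible(x)
}
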