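#' Pipeline configuration
#'
#' Assembles (and validates the shape of) the configuration for
#' [run_pipeline()]. All analysis parameters are exposed here with the
#' package defaults.
#'
#' @param events Path to the event-log CSV.
#' @param categories Path to the category CSV.
#' @param output_dir Directory for per-stage outputs (created if missing).
#' @param session_gap_threshold Session inactivity threshold, minutes.
#' @param min_views Activity filter for the clustering stage.
#' @param k Cluster count, or `"auto"` for elbow selection.
#' @param k_range Candidate `k` values when `k = "auto"`.
#' @param restarts K-means restarts.
#' @param periodicity_min_events,periodicity_dominance_ratio,periodicity_min_power_fraction
#'   Thresholds of [detect_periodicity()].
#' @param rr_min Relative-risk cutoff of [filter_core()].
#' @param seed Seed for the stochastic stages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(events, categories, output_dir = "forumdyn_out",
                            session_gap_threshold = 60, min_views = 100,
                            k = "auto", k_range = 2:15, restarts = 10L,
                            periodicity_min_events = 50,
                            periodicity_dominance_ratio = 2.0,
                            periodicity_min_power_fraction = 0.10,
                            rr_min = 1.0, seed = 1L) {
  structure(list(
    events = events, categories = categories, output_dir = output_dir,
    session_gap_threshold = session_gap_threshold, min_views = min_views,
    k = k, k_range = k_range, restarts = as.integer(restarts),
    periodicity_min_events = periodicity_min_events,
    periodicity_dominance_ratio = periodicity_dominance_ratio,
    periodicity_min_power_fraction = periodicity_min_power_fraction,
    rr_min = rr_min, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()]; `k_range` may be given as `[lo, hi]`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$k_range) && length(y$k_range) == 2L) {
    y$k_range <- seq(y$k_range[[1L]], y$k_range[[2L]])
  }
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on an event log: descriptive summary,
#' session segmentation and duration statistics, weekly-profile
#' periodicity classification with a per-role census, preference
#' clustering (elbow-selected or fixed `k`) with per-cluster entropy, and
#' the relative-risk category network with COPINE core composition.
#' Per-stage tables are written under `output_dir` together with a
#' machine-readable `report.json`; the report is identical for identical
#' config and seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return The report, invisibly: a nested list with elements
#'   `meta`, `descriptive`, `sessions`, `periodicity`, `clusters`,
#'   `network`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage ", sQuote(name), " failed: ", conditionMessage(e))
    })
  }
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name) {
    message(sprintf("[forumdyn] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed, config_hash = config_hash(config))

  events <- stage("load", read_event_log(config$events))
  categories <- stage("load", {
    if (!file.exists(config$categories)) {
      stop_("network stage input missing: category table ",
            sQuote(config$categories))
    }
    read_categories(config$categories)
  })
  log_stage("load")

  descr <- stage("descriptive", descriptive_summary(events))
  log_stage("descriptive")

  sessions <- stage("sessions", sessionize(events, config$session_gap_threshold))
  gaps <- stage("sessions", {
    ts <- split(as.numeric(events$timestamp), events$user_id)
    unlist(lapply(ts, function(x) if (length(x) > 1L) diff(x) / 60),
           use.names = FALSE)
  })
  sess_stats <- stage("sessions",
                      session_duration_stats(sessions, c(10, 60), gaps))
  data.table::fwrite(
    sessions[, .(user_id, session_id,
                 start = format(start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                 end = format(end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                 n_events, duration_min)],
    file.path(config$output_dir, "sessions.csv"))
  log_stage("sessions")

  periodicity <- stage("temporal", classify_periodicities(
    events, config$periodicity_min_events,
    config$periodicity_dominance_ratio,
    config$periodicity_min_power_fraction))
  roles <- stage("temporal", data.table::rbindlist(list(
    data.table::data.table(
      user_id = unique(events[event_type == "view", user_id]),
      role = "consumer"),
    data.table::data.table(
      user_id = unique(events[event_type == "post", user_id]),
      role = "producer")
  )))
  census <- stage("temporal", periodicity_census(periodicity, roles))
  data.table::fwrite(periodicity,
                     file.path(config$output_dir, "periodicity.csv"))
  log_stage("temporal")

  clusters <- stage("clusters", {
    mat <- build_view_share_matrix(events, config$min_views)
    curve <- NULL
    if (identical(config$k, "auto")) {
      curve <- kmeans_inertia_curve(mat, config$k_range, config$seed,
                                    config$restarts)
      k <- as.integer(select_k_elbow(curve))
    } else {
      k <- as.integer(config$k)
    }
    fit <- cluster_users(mat, k, config$seed, config$restarts)
    ent <- cluster_entropy_summary(fit, mat)
    list(matrix = mat, inertia_curve = curve, k = k, fit = fit, entropy = ent)
  })
  data.table::fwrite(clusters$entropy$per_user,
                     file.path(config$output_dir, "clusters.csv"))
  log_stage("clusters")

  network <- stage("network", {
    tab <- consumption_table(events)
    net <- build_rr_network(tab, categories)
    core_net <- filter_core(net, config$rr_min)
    comp <- core_composition(core_net)
    data.table::fwrite(core_net$edges,
                       file.path(config$output_dir, "edges.csv"))
    igraph::write_graph(as_igraph(core_net),
                        file.path(config$output_dir, "network.graphml"),
                        format = "graphml")
    list(network = net, filtered = core_net, composition = comp)
  })
  log_stage("network")

  report <- list(
    meta = meta,
    descriptive = list(
      n_users = descr$n_users, n_posts = descr$n_posts,
      n_views = descr$n_views, n_categories = descr$n_categories,
      mean_distinct_categories_viewed =
        mean(descr$unique_categories_viewed_per_user),
      mean_posts_per_producer =
        if (length(descr$posts_per_user)) mean(descr$posts_per_user) else NA
    ),
    sessions = list(
      n_sessions = sess_stats$n_sessions,
      mean_duration_min = sess_stats$mean_duration,
      survival_at = as.list(sess_stats$survival_at)
    ),
    periodicity = list(census = census),
    clusters = list(
      k = clusters$k,
      inertia_curve = as.list(clusters$inertia_curve),
      entropy_per_cluster = clusters$entropy$per_cluster
    ),
    network = list(
      n_nodes = nrow(network$filtered$nodes),
      n_edges = nrow(network$filtered$edges),
      k_max = network$composition$k_max,
      core_fractions = as.list(network$composition$fractions)
    )
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
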