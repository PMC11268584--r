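#' User-by-category view-share matrix
#'
#' Builds the feature matrix for preference clustering: per-user counts of
#' view events in each category, restricted to users with at least
#' `min_views` views (low-activity users carry too little signal to
#' profile), and the row-normalised shares. Shares rather than raw counts
#' remove activity-volume confounding, so clusters reflect what a user
#' views, not how much.
#'
#' @param events Event table; only `view` events contribute.
#' @param min_views Minimum total views for a user to be retained;
#'   default 100.
#' @return A list of class `"user_category_matrix"`: `user_ids`,
#'   `category_ids`, `counts` (users x categories integer matrix) and
#'   `shares` (rows summing to 1).
#' @export
build_view_share_matrix <- function(events, min_views = 100) {
  events <- data.table::as.data.table(events)
  views <- events[event_type == "view"]
  if (nrow(views) == 0L) stop_("no view events")
  cats <- sort(unique(views$category_id))
  tab <- views[, .N, by = .(user_id, category_id)]
  totals <- tab[, .(total = sum(N)), by = user_id]
  keep <- totals[total >= min_views, user_id]
  if (length(keep) == 0L) {
    stop_("no user has at least ", min_views, " views")
  }
  keep <- sort(keep)
  counts <- matrix(0L, length(keep), length(cats),
                   dimnames = list(keep, cats))
  tab <- tab[user_id %in% keep]
  counts[cbind(match(tab$user_id, keep), match(tab$category_id, cats))] <- tab$N
  structure(list(
    user_ids = keep,
    category_ids = cats,
    counts = counts,
    shares = counts / rowSums(counts)
  ), class = "user_category_matrix")
}

#' K-means inertia curve over a range of cluster counts
#'
#' Fits k-means (k-means++ seeding, best of `restarts`) to the share matrix
#' for each candidate `k` and records the within-cluster sum of squares.
#'
#' @param matrix_ A [build_view_share_matrix()] result.
#' @param k_range Candidate cluster counts; default `2:15`.
#' @param seed Integer seed making the whole curve reproducible.
#' @param restarts Restarts per `k`; default 10.
#' @return Named numeric vector: inertia (total within-cluster sum of
#'   squares) per `k`.
#' @export
kmeans_inertia_curve <- function(matrix_, k_range = 2:15, seed = 1L,
                                 restarts = 10L) {
  x <- matrix_$shares
  if (nrow(x) < max(k_range)) {
    stop_("k_range upper end (", max(k_range), ") exceeds the number of ",
          "retained users (", nrow(x), ")")
  }
  set.seed(seed)
  inertia <- vapply(k_range, function(k) kmeans_best(x, k, restarts)$tot.withinss,
                    numeric(1))
  stats::setNames(inertia, k_range)
}

#' Elbow selection of the cluster count
#'
#' Selects the `k` at which the inertia curve bends most sharply: the
#' interior `k` maximising the second difference
#' `inertia[k-1] - 2*inertia[k] + inertia[k+1]`, with ties broken toward
#' smaller `k`. A flat or strictly linear curve has no elbow; the smallest
#' `k` is returned with attribute `flat = TRUE` and a warning.
#'
#' @param inertia_curve Named numeric vector (names are consecutive `k`
#'   values), as from [kmeans_inertia_curve()]; at least 4 points.
#' @return Integer `k`, with attributes `flat` (logical) and
#'   `second_differences` (named numeric over the interior `k`).
#' @export
select_k_elbow <- function(inertia_curve) {
  ks <- as.integer(names(inertia_curve))
  if (length(ks) < 4L || any(diff(ks) != 1L)) {
    stop_("inertia curve must cover at least 4 consecutive k values")
  }
  d2 <- diff(diff(inertia_curve))          # second difference at ks[2..m-1]
  names(d2) <- ks[2:(length(ks) - 1L)]
  tol <- 1e-12 * max(abs(inertia_curve), 1)
  if (max(d2) <= tol) {
    warning("inertia curve has no curvature; returning smallest k",
            call. = FALSE)
    return(structure(ks[1L], flat = TRUE, second_differences = d2))
  }
  k_sel <- as.integer(names(d2)[which.max(d2)])  # first max: smaller k wins ties
  structure(k_sel, flat = FALSE, second_differences = d2)
}

#' Cluster users by category preferences
#'
#' K-means on the view-share matrix with k-means++ seeding, keeping the
#' best of `restarts` by within-cluster sum of squares.
#'
#' @param matrix_ A [build_view_share_matrix()] result.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param restarts Number of restarts; default 10.
#' @return A list of class `"forum_clustering"`: `k`, `assignments` (named
#'   integer vector, user id -> cluster in `1..k`), `inertia`, `centers`
#'   and `seed`.
#' @export
cluster_users <- function(matrix_, k, seed = 1L, restarts = 10L) {
  if (k < 2L) stop_("k must be at least 2")
  x <- matrix_$shares
  if (nrow(x) < k) stop_("fewer retained users than clusters")
  set.seed(seed)
  fit <- kmeans_best(x, k, restarts)
  structure(list(
    k = as.integer(k),
    assignments = stats::setNames(fit$cluster, matrix_$user_ids),
    inertia = fit$tot.withinss,
    centers = fit$centers,
    seed = as.integer(seed)
  ), class = "forum_clustering")
}

#' Shannon entropy of a preference distribution
#'
#' `H = -sum(p * log2(p))` in bits, with `0 * log 0 = 0`. Ranges from 0
#' (all views in one category) to `log2(M)` (uniform over `M` categories).
#'
#' @param shares Non-negative vector summing to 1 (tolerance 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(shares) {
  if (any(shares < 0)) stop_("shares must be non-negative")
  if (abs(sum(shares) - 1) > 1e-9) stop_("shares must sum to 1")
  p <- shares[shares > 0]
  -sum(p * log2(p))
}

#' Entropy profile of preference clusters
#'
#' Computes each retained user's preference entropy and summarises the
#' distribution of member entropies within each cluster, separating groups
#' with broad preferences (high entropy) from narrow ones (low entropy).
#'
#' @param clustering A [cluster_users()] result.
#' @param matrix_ The [build_view_share_matrix()] the clustering was fit on.
#' @return A list of class `"entropy_summary"`: `per_user` (a `data.table`
#'   with `user_id`, `cluster`, `entropy_bits`) and `per_cluster`
#'   (`cluster`, `n`, `mean`, `q25`, `median`, `q75`).
#' @export
cluster_entropy_summary <- function(clustering, matrix_) {
  if (!identical(names(clustering$assignments),
                 as.character(matrix_$user_ids))) {
    stop_("clustering and matrix refer to different users")
  }
  ent <- apply(matrix_$shares, 1L, shannon_entropy)
  per_user <- data.table::data.table(
    user_id = matrix_$user_ids,
    cluster = unname(clustering$assignments),
    entropy_bits = unname(ent)
  )
  per_cluster <- per_user[, .(
    n = .N,
    mean = mean(entropy_bits),
    q25 = unname(stats::quantile(entropy_bits, 0.25)),
    median = stats::median(entropy_bits),
    q75 = unname(stats::quantile(entropy_bits, 0.75))
  ), by = cluster]
  data.table::setorder(per_cluster, cluster)
  structure(list(per_user = per_user, per_cluster = per_cluster[]),
            class = "entropy_summary")
}
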