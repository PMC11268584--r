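test_that("view-share matrix normalises rows and filters inactive users", {
  ev <- data.table::rbindlist(list(
    events_at_minutes(c(0, 1, 2), user_id = 1, category_id = 1),
    events_at_minutes(3, user_id = 1, category_id = 2),
    events_at_minutes(c(0, 1, 2, 3, 4), user_id = 2, category_id = 2)
  ))
  m <- build_view_share_matrix(ev, min_views = 1)
  expect_equal(unname(m$shares[1, ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(m$shares)), rep(1, 2))

  m2 <- build_view_share_matrix(ev, min_views = 5)
  expect_false(1L %in% m2$user_ids)  # 4 views < 5
  expect_error(build_view_share_matrix(ev, min_views = 100), "at least 100")
  # posts never contribute
  ev_post <- data.table::copy(ev)[, event_type := "post"]
  expect_error(build_view_share_matrix(ev_post), "no view events")
})

test_that("shannon entropy matches closed forms and stays within bounds", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.7, 0.2)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")

  set.seed(51)
  for (rep in 1:50) {
    m <- sample(2:30, 1)
    p <- rgamma(m, sample(c(0.2, 1, 5), 1))
    p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(m) + 1e-12)
  }
})

test_that("elbow selection follows the maximum second difference with flat fallback", {
  # second differences over k = 2..4: (25, 24, 0); the maximum, 25, is at k = 2
  expect_equal(as.integer(select_k_elbow(
    stats::setNames(c(100, 50, 25, 24, 23), 1:5))), 2L)
  # a sharp single bend is found wherever it sits
  expect_equal(as.integer(select_k_elbow(
    stats::setNames(c(400, 300, 200, 100, 95, 92), 2:7))), 5L)
  # strictly linear curve: no curvature, smallest k with flat flag
  expect_warning(
    kflat <- select_k_elbow(stats::setNames(c(40, 30, 20, 10), 2:5)),
    "no curvature")
  expect_equal(as.integer(kflat), 2L)
  expect_true(attr(kflat, "flat"))
  expect_error(select_k_elbow(stats::setNames(c(3, 2, 1), 2:4)), "at least 4")
})

test_that("inertia is zero with one cluster per distinct row and decreases in k", {
  set.seed(52)
  proto <- matrix(runif(4 * 6), 4, 6)
  x <- proto[rep(1:4, each = 5), ]
  m <- list(user_ids = 1:20, category_ids = 1:6,
            counts = x, shares = x / rowSums(x))
  class(m) <- "user_category_matrix"
  curve <- kmeans_inertia_curve(m, k_range = 2:6, seed = 1)
  expect_equal(unname(curve[["4"]]), 0, tolerance = 1e-12)
  expect_true(all(diff(curve) <= 1e-8))
  expect_error(kmeans_inertia_curve(m, k_range = 2:50, seed = 1), "exceeds")
})

test_that("well-separated clouds are recovered and duplicated rows co-assigned", {
  set.seed(53)
  centers <- diag(2)
  x <- rbind(matrix(rep(centers[1, ], 15), ncol = 2, byrow = TRUE),
             matrix(rep(centers[2, ], 15), ncol = 2, byrow = TRUE)) +
    matrix(rnorm(60, sd = 0.03), ncol = 2)
  x <- abs(x) / rowSums(abs(x))
  m <- list(user_ids = 1:30, category_ids = 1:2, counts = x, shares = x)
  class(m) <- "user_category_matrix"
  fit <- cluster_users(m, 2, seed = 9)
  truth <- rep(1:2, each = 15)
  expect_equal(adjusted_rand(fit$assignments, truth), 1)
  expect_error(cluster_users(m, 1, seed = 9), "at least 2")

  # exactly duplicated rows always land in the same cluster
  dup <- x[rep(1:5, 4), ]
  md <- list(user_ids = 1:20, category_ids = 1:2, counts = dup, shares = dup)
  class(md) <- "user_category_matrix"
  fd <- cluster_users(md, 2, seed = 9)
  groups <- split(unname(fd$assignments), rep(1:5, 4))
  expect_true(all(vapply(groups, function(g) length(unique(g)) == 1L,
                         logical(1))))
})

test_that("row permutation permutes assignments identically", {
  sim <- simulate_forum(forum_config(n_users = 300), seed = 54)
  mat <- build_view_share_matrix(sim$events)
  fit <- cluster_users(mat, 8, seed = 3)

  perm <- sample(nrow(mat$shares))
  mat_p <- mat
  mat_p$shares <- mat$shares[perm, ]
  mat_p$counts <- mat$counts[perm, ]
  mat_p$user_ids <- mat$user_ids[perm]
  fit_p <- cluster_users(mat_p, 8, seed = 3)
  expect_equal(adjusted_rand(fit$assignments[as.character(mat_p$user_ids)],
                             fit_p$assignments), 1)
})

test_that("test helper agreement score matches mclust's adjusted Rand index", {
  set.seed(55)
  for (rep in 1:5) {
    a <- sample.int(4, 60, replace = TRUE)
    b <- sample.int(3, 60, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("cluster entropy summaries separate narrow from broad archetypes", {
  sim <- simulate_forum(forum_config(n_users = 500), seed = 56)
  mat <- build_view_share_matrix(sim$events)
  fit <- cluster_users(mat, 8, seed = 5)
  ent <- cluster_entropy_summary(fit, mat)

  expect_equal(sort(unique(ent$per_user$cluster)), 1:8)
  expect_true(all(ent$per_user$entropy_bits >= 0))
  expect_true(all(ent$per_user$entropy_bits <= log2(ncol(mat$shares)) + 1e-9))

  # archetypes 1-3 are the low-concentration (narrow) ones by construction
  truth <- sim$population$users[match(mat$user_ids, user_id), archetype]
  narrow_mean <- mean(ent$per_user$entropy_bits[truth <= 3])
  broad_mean <- mean(ent$per_user$entropy_bits[truth > 3])
  expect_lt(narrow_mean, broad_mean)

  # a cluster of single-category viewers has zero mean entropy
  x <- diag(3)[rep(1:3, each = 4), ]
  md <- list(user_ids = 1:12, category_ids = 1:3, counts = x, shares = x)
  class(md) <- "user_category_matrix"
  fd <- cluster_users(md, 3, seed = 1)
  e0 <- cluster_entropy_summary(fd, md)
  expect_equal(e0$per_cluster$mean, rep(0, 3))
})
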