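toy_categories <- function(ids, grades) {
  data.table::data.table(category_id = ids,
                         label = sprintf("cat_%02d", ids),
                         copine_grade = grades,
                         segment = copine_segment(grades))
}

# events where each user views each listed category once
views_of <- function(user_cats) {
  data.table::rbindlist(lapply(seq_along(user_cats), function(u) {
    events_at_minutes(seq_along(user_cats[[u]]), user_id = u,
                      category_id = user_cats[[u]])
  }))
}

test_that("consumption table counts distinct viewers with set semantics", {
  # u1 views {1,2}, u2 views {1}, u3 views {2}
  tab <- consumption_table(views_of(list(c(1, 2), 1, 2)))
  expect_equal(tab$n_users, 3L)
  expect_equal(unname(tab$prevalence[c("1", "2")]), c(2L, 2L))

  # repeated views by one user count once
  rep_ev <- events_at_minutes(1:10, user_id = 1, category_id = 3)
  tab2 <- consumption_table(rep_ev)
  expect_equal(unname(tab2$prevalence[["3"]]), 1L)
  expect_error(consumption_table(rep_ev[0]), "no view")
})

test_that("relative risk follows C*N/(Pi*Pj)", {
  expect_equal(relative_risk(25, 100, 50, 50), 1.0)
  expect_equal(relative_risk(40, 100, 50, 50), 1.6)
  expect_equal(relative_risk(0, 100, 50, 50), 0)
  expect_equal(relative_risk(3, 7, 4, 5), relative_risk(3, 7, 5, 4))
  expect_error(relative_risk(10, 100, 0, 50), "prevalence")
  expect_error(relative_risk(60, 100, 50, 50), "c_ij")
})

test_that("the toy network carries the worked-out edge and drops empty pairs", {
  ev <- views_of(list(c(1, 2), 1, 2))
  net <- build_rr_network(consumption_table(ev), toy_categories(1:2, c(3, 8)))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$c_ij, 1L)
  expect_equal(net$edges$rr, 1 * 3 / (2 * 2))
  expect_equal(net$nodes$segment, c("NonSexual", "Sexual"))
  expect_false(net$filtered)

  # disjoint audiences: no edge
  net2 <- build_rr_network(consumption_table(views_of(list(1, 2))),
                           toy_categories(1:2, c(3, 8)))
  expect_equal(nrow(net2$edges), 0L)

  expect_error(build_rr_network(consumption_table(ev), toy_categories(1, 3)),
               "not in the category table")
})

test_that("every RR matches brute-force set intersection on random toy logs", {
  set.seed(61)
  for (rep in 1:25) {
    n_users <- sample(2:10, 1)
    n_cats <- sample(2:6, 1)
    ev <- random_event_log(sample(10:60, 1), n_users = n_users,
                           n_categories = n_cats)
    ev <- ev[event_type == "view"]
    if (nrow(ev) == 0L) next
    tab <- consumption_table(ev)
    net <- build_rr_network(tab, toy_categories(1:n_cats,
                                                rep(c(2, 9), length.out = n_cats)))
    sets <- lapply(split(ev$category_id, ev$user_id), unique)
    n_viewers <- length(sets)
    for (r in seq_len(nrow(net$edges))) {
      i <- net$edges$category_i[r]; j <- net$edges$category_j[r]
      c_ij <- sum(vapply(sets, function(s) i %in% s && j %in% s, logical(1)))
      p_i <- sum(vapply(sets, function(s) i %in% s, logical(1)))
      p_j <- sum(vapply(sets, function(s) j %in% s, logical(1)))
      expect_equal(net$edges$c_ij[r], c_ij)
      expect_equal(net$edges$rr[r], c_ij * n_viewers / (p_i * p_j))
    }
    # no pair with a shared consumer is missing
    n_pairs_expected <- sum(vapply(seq_len(n_cats - 1), function(i) {
      sum(vapply((i + 1):n_cats, function(j) {
        any(vapply(sets, function(s) i %in% s && j %in% s, logical(1)))
      }, logical(1)))
    }, numeric(1)))
    expect_equal(nrow(net$edges), n_pairs_expected)
  }
})

test_that("filtering keeps the RR = 1 boundary, drops isolated nodes, and is idempotent", {
  ev <- data.table::rbindlist(lapply(1:20, function(u) {
    cats <- switch(1 + u %% 4, c(1, 2), c(1, 2, 3), c(2, 3), 4)
    events_at_minutes(seq_along(cats), user_id = u, category_id = cats)
  }))
  net <- build_rr_network(consumption_table(ev),
                          toy_categories(1:4, c(2, 8, 9, 5)))
  f1 <- filter_core(net, rr_min = 1)
  expect_true(all(f1$edges$rr >= 1))
  deg <- table(c(f1$edges$category_i, f1$edges$category_j))
  expect_true(all(f1$nodes$category_id %in% as.integer(names(deg))))
  f2 <- filter_core(f1, rr_min = 1)
  expect_equal(f2, f1)
  expect_lte(nrow(f1$edges), nrow(net$edges))
  expect_lte(nrow(f1$nodes), nrow(net$nodes))

  # a node whose only edge fails the cutoff disappears with it
  net_weak <- net
  net_weak$edges <- data.table::data.table(category_i = 1L, category_j = 4L,
                                           c_ij = 1L, rr = 0.5)
  f3 <- filter_core(net_weak, rr_min = 1)
  expect_equal(nrow(f3$nodes), 0L)
  expect_equal(nrow(f3$edges), 0L)
})

test_that("empirical RR under independent consumption converges to 1", {
  set.seed(62)
  n <- 20000
  a <- runif(n) < 0.3
  b <- runif(n) < 0.4
  # everyone also views a background category so N covers the population
  ev <- data.table::rbindlist(list(
    events_at_minutes(rep(0, n), user_id = 1:n, category_id = 3),
    events_at_minutes(rep(1, sum(a)), user_id = which(a), category_id = 1),
    events_at_minutes(rep(2, sum(b)), user_id = which(b), category_id = 2)
  ))
  tab <- consumption_table(ev)
  expect_equal(tab$n_users, n)
  net <- build_rr_network(tab, toy_categories(1:3, c(8, 2, 2)))
  rr <- net$edges[category_i == 1 & category_j == 2, rr]
  expect_equal(rr, 1, tolerance = 0.05)
})

test_that("k-core composition isolates a planted clique and handles trees", {
  # 4-clique of Sexual categories with 3 NonSexual pendants
  users <- c(lapply(1:12, function(i) 1:4),       # clique co-consumers
             list(c(1, 5), c(2, 6), c(3, 7)))
  ev <- views_of(users)
  net <- build_rr_network(consumption_table(ev),
                          toy_categories(1:7, c(rep(9, 4), rep(2, 3))))
  net$filtered <- TRUE   # keep all edges; composition is about the k-core
  comp <- core_composition(net)
  expect_equal(sort(comp$core_nodes), 1:4)
  expect_equal(comp$fractions[["Sexual"]], 1)
  expect_equal(comp$fractions[["NonSexual"]], 0)
  expect_gte(comp$k_max, 3)

  # a star is one big 1-core
  star <- views_of(lapply(2:5, function(leaf) c(1, leaf)))
  snet <- build_rr_network(consumption_table(star),
                           toy_categories(1:5, c(8, 2, 2, 2, 2)))
  snet$filtered <- TRUE
  scomp <- core_composition(snet)
  expect_equal(scomp$k_max, 1L)
  expect_equal(sort(scomp$core_nodes), 1:5)

  expect_error(core_composition(build_rr_network(
    consumption_table(star), toy_categories(1:5, c(8, 2, 2, 2, 2)))),
    "filtered")
})

test_that("the generated forum's innermost core is dominated by the Sexual segment", {
  sim <- simulate_forum(forum_config(), seed = 63)
  net <- build_rr_network(consumption_table(sim$events), sim$categories)
  comp <- core_composition(filter_core(net))
  expect_gte(comp$fractions[["Sexual"]], comp$fractions[["NonSexual"]])
})
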