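#' Per-category consumer sets
#'
#' Consumption is defined by viewing: a user has consumed a category if
#' they viewed content in it at least once. Repeated views count once.
#'
#' @param events Event table; only `view` events contribute.
#' @return A list of class `"consumption_table"`: `n_users` (distinct
#'   viewing users, the `N` of the relative-risk formula), `consumers`
#'   (named list, category id -> sorted vector of user ids) and
#'   `prevalence` (named integer vector `P`, consumers per category).
#' @export
consumption_table <- function(events) {
  events <- data.table::as.data.table(events)
  views <- events[event_type == "view"]
  if (nrow(views) == 0L) stop_("no view events")
  pairs <- unique(views[, .(user_id, category_id)])
  consumers <- lapply(split(pairs$user_id, pairs$category_id), sort)
  structure(list(
    n_users = data.table::uniqueN(views$user_id),
    consumers = consumers,
    prevalence = stats::setNames(lengths(consumers), names(consumers))
  ), class = "consumption_table")
}

#' Relative risk of category co-consumption
#'
#' `RR_ij = C_ij * N / (P_i * P_j)`, the ratio of observed co-consumption
#' to that expected if consumption of the two categories were independent:
#' `RR = 1` means no association, `RR > 1` a positive association, and
#' `RR < 1` fewer shared consumers than expected.
#'
#' @param c_ij Number of users who consumed both categories.
#' @param n Total number of users considered.
#' @param p_i,p_j Prevalence (consumer count) of each category.
#' @return The relative risk (vectorised over its arguments).
#' @export
relative_risk <- function(c_ij, n, p_i, p_j) {
  if (any(n <= 0)) stop_("n must be positive")
  if (any(p_i <= 0) || any(p_j <= 0)) stop_("prevalence must be positive")
  if (any(c_ij < 0) || any(c_ij > pmin(p_i, p_j))) {
    stop_("c_ij must satisfy 0 <= c_ij <= min(p_i, p_j)")
  }
  c_ij * n / (p_i * p_j)
}

#' Build the category co-consumption network
#'
#' Categories are nodes; an edge joins every unordered pair of categories
#' sharing at least one consumer, weighted by [relative_risk()]. Nodes
#' carry the COPINE segment from the category table.
#'
#' @param table_ A [consumption_table()].
#' @param categories Category table (see [read_categories()]); every
#'   category appearing in the events must be present.
#' @return A list of class `"category_network"`: `nodes` (a `data.table`
#'   with `category_id`, `label`, `copine_grade`, `segment`, `prevalence`),
#'   `edges` (`category_i < category_j`, `c_ij`, `rr`), `n_users` and
#'   `filtered = FALSE`.
#' @export
build_rr_network <- function(table_, categories) {
  categories <- data.table::as.data.table(categories)
  if (!"segment" %in% names(categories)) {
    categories[, segment := copine_segment(copine_grade)]
  }
  cat_ids <- as.integer(names(table_$consumers))
  missing <- setdiff(cat_ids, categories$category_id)
  if (length(missing)) {
    stop_("categories in events but not in the category table: ",
          paste(missing, collapse = ", "))
  }
  # incidence crossproduct gives all pairwise co-consumer counts at once
  users <- sort(unique(unlist(table_$consumers, use.names = FALSE)))
  inc <- matrix(0L, length(users), length(cat_ids))
  for (j in seq_along(cat_ids)) {
    inc[match(table_$consumers[[j]], users), j] <- 1L
  }
  co <- crossprod(inc)
  pair <- which(upper.tri(co) & co >= 1, arr.ind = TRUE)
  prev <- as.numeric(table_$prevalence)
  edges <- data.table::data.table(
    category_i = cat_ids[pair[, 1L]],
    category_j = cat_ids[pair[, 2L]],
    c_ij = as.integer(co[pair]),
    rr = relative_risk(co[pair], table_$n_users,
                       prev[pair[, 1L]], prev[pair[, 2L]])
  )
  data.table::setorder(edges, category_i, category_j)
  nodes <- categories[category_id %in% cat_ids,
                      .(category_id, label, copine_grade, segment)]
  nodes[, prevalence := as.integer(table_$prevalence[as.character(category_id)])]
  data.table::setorder(nodes, category_id)
  structure(list(nodes = nodes[], edges = edges[], n_users = table_$n_users,
                 filtered = FALSE), class = "category_network")
}

#' Filter the network to its associated core
#'
#' Removes edges with relative risk below `rr_min` (the boundary value is
#' retained) and then removes nodes left without any edge. Idempotent.
#'
#' @param network A [build_rr_network()] result.
#' @param rr_min Relative-risk cutoff; default 1 (drop sub-independence
#'   links).
#' @return The filtered `category_network` (`filtered = TRUE`).
#' @export
filter_core <- function(network, rr_min = 1.0) {
  edges <- network$edges[rr >= rr_min]
  connected <- union(edges$category_i, edges$category_j)
  nodes <- network$nodes[category_id %in% connected]
  structure(list(nodes = nodes, edges = edges, n_users = network$n_users,
                 filtered = TRUE), class = "category_network")
}

#' Convert a category network to igraph
#'
#' @param network A `category_network`.
#' @return An undirected [igraph::graph] whose vertices carry `label`,
#'   `copine_grade`, `segment` and `coreness`.
#' @export
as_igraph <- function(network) {
  nodes <- data.table::copy(network$nodes)
  data.table::setnames(nodes, "category_id", "name")
  nodes[, name := as.character(name)]
  edges <- network$edges[, .(from = as.character(category_i),
                             to = as.character(category_j), c_ij,
                             weight = rr)]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::V(g)$coreness <- igraph::coreness(g)
  g
}

#' COPINE composition of the network's innermost core
#'
#' Runs a k-core decomposition of the (unweighted) filtered network and
#' reports the COPINE-segment make-up of the maximum-k core --- the
#' subgraph in which every category still has at least `k_max` co-consumed
#' neighbours. A core dominated by the Sexual segment with NonSexual
#' categories at the periphery indicates that severe content is what the
#' user groups share.
#'
#' @param network A filtered `category_network` (see [filter_core()]).
#' @return A list of class `"core_composition"`: `k_max`, `core_nodes`
#'   (category ids of the maximum core), `fractions` (named: share of the
#'   maximum core in each segment), `n_core` and `coreness` (named integer
#'   vector over all nodes).
#' @export
core_composition <- function(network) {
  if (!isTRUE(network$filtered)) {
    stop_("core_composition() expects a filtered network; call filter_core()")
  }
  if (nrow(network$nodes) == 0L) stop_("empty network")
  g <- as_igraph(network)
  core <- igraph::coreness(g)
  k_max <- max(core)
  in_core <- names(core)[core == k_max]
  seg <- network$nodes[match(as.integer(in_core), category_id), segment]
  fractions <- vapply(c(NonSexual = "NonSexual", Sexual = "Sexual"),
                      function(s) mean(seg == s), numeric(1))
  structure(list(
    k_max = k_max,
    core_nodes = as.integer(in_core),
    fractions = fractions,
    n_core = length(in_core),
    coreness = stats::setNames(as.integer(core), names(core))
  ), class = "core_composition")
}

#' @export
print.core_composition <- function(x, ...) {
  cat(sprintf("Maximum k-core: k = %d, %d categories\n", x$k_max, x$n_core))
  cat(sprintf("  Sexual: %.1f%%   NonSexual: %.1f%%\n",
              100 * x$fractions[["Sexual"]], 100 * x$fractions[["NonSexual"]]))
  invisible(x)
}
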