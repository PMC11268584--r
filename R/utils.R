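# internal numerical helpers shared across modules

# Dirichlet sampler via normalised gammas; alpha strictly positive
rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(x)
  if (s <= 0) {
    # numerically degenerate draw (all-zero gammas for tiny alpha): put all
    # mass on one coordinate chosen by alpha
    out <- numeric(length(alpha))
    out[sample.int(length(alpha), 1L, prob = alpha)] <- 1
    return(out)
  }
  x / s
}

# lognormal truncated ABOVE at `upper`, inverse-CDF sampling (exact, vectorised)
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  pu <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n) * pu, meanlog, sdlog)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# squared-distance weighted sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    cand <- which(d2 > 1e-12)   # only points distinct from chosen centers
    if (length(cand) == 0L) {
      stop_("more cluster centers requested than distinct data points")
    }
    pick <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L, prob = d2[cand])]
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

# best-of-restarts k-means with k-means++ seeding; depends on the current
# RNG state, so callers set the seed
kmeans_best <- function(x, k, restarts) {
  ux <- unique(x)
  if (k >= nrow(ux)) {
    # at least one center per distinct point: zero-inertia exact fit
    assign <- match(apply(x, 1L, paste, collapse = "\r"),
                    apply(ux, 1L, paste, collapse = "\r"))
    return(list(cluster = assign, centers = ux, tot.withinss = 0))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- suppressWarnings(
      stats::kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100L)
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
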