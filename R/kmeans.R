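#' K-means clustering with k-means++ seeding
#'
#' Lloyd iterations from a k-means++-style initialization: the first
#' centre is a uniformly drawn point, each further centre is drawn with
#' probability proportional to the squared distance to the nearest chosen
#' centre. The within-cluster sum of squares is asserted non-increasing at
#' every iteration; a cluster that empties is re-seeded from the point
#' farthest from its centre. Deterministic under a fixed seed. Cluster
#' labels are `0..k-1` character strings, matching the subpopulation
#' naming used downstream (C0..C7 for the default k = 8).
#'
#' @param embedding Numeric matrix, cells (rows) x dimensions; row names
#'   are carried into the assignment.
#' @param k Number of clusters (>= 2, <= rows).
#' @param seed Integer seed.
#' @param max_iter Maximum Lloyd iterations.
#' @param nstart Independent k-means++ restarts; the solution with the
#'   lowest within-cluster sum of squares is kept.
#' @return An object of class `cr_kmeans`: list with `assignment` (tibble
#'   `barcode`, `cluster`), `centers`, `tot_withinss`, `objective_trace`,
#'   `iterations`, `k`, `seed`.
#' @export
kmeans_cluster <- function(embedding, k = 8L, seed = 1L, max_iter = 100L,
                           nstart = 10L) {
  embedding <- as.matrix(embedding)
  if (k < 2L) abort("k must be >= 2.")
  if (k > nrow(embedding)) abort("k cannot exceed the number of cells.")
  set.seed(seed)
  best <- NULL
  for (run in seq_len(nstart)) {
    fit <- kmeans_single(embedding, k, max_iter)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  barcodes <- rownames(embedding) %||% as.character(seq_len(nrow(embedding)))
  structure(
    list(
      assignment = tibble(barcode = barcodes,
                          cluster = as.character(best$assign - 1L)),
      centers = best$centers,
      tot_withinss = best$tot_withinss,
      objective_trace = best$trace,
      iterations = length(best$trace),
      k = k, seed = seed
    ),
    class = "cr_kmeans")
}

kmeans_single <- function(embedding, k, max_iter) {
  n <- nrow(embedding)
  centers <- embedding[kmeanspp_init(embedding, k), , drop = FALSE]
  trace <- numeric(0)
  assign_old <- rep(-1L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- pairwise_sqdist(embedding, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the globally farthest point
    for (c_i in which(tabulate(assign_new, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), assign_new)])
      centers[c_i, ] <- embedding[far, ]
      d2 <- pairwise_sqdist(embedding, centers)
      assign_new <- max.col(-d2, ties.method = "first")
    }
    obj <- sum(d2[cbind(seq_len(n), assign_new)])
    if (length(trace) > 0L && obj > utils::tail(trace, 1) + 1e-8 * (1 + obj)) {
      abort("k-means objective increased; this indicates a numerical fault.")
    }
    trace <- c(trace, obj)
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (c_i in seq_len(k)) {
      centers[c_i, ] <- colMeans(embedding[assign_new == c_i, , drop = FALSE])
    }
  }
  list(assign = assign_new, centers = centers,
       tot_withinss = utils::tail(trace, 1), trace = trace)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
  for (i in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    idx[i] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[i], ], "-")^2))
  }
  idx
}

pairwise_sqdist <- function(x, centers) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, clipped at 0 for roundoff
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) - 2 * cross +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  pmax(d2, 0)
}

#' @export
print.cr_kmeans <- function(x, ...) {
  cat(sprintf("k-means clustering: %d cells, k = %d, total WSS = %.2f (%d iterations)\n",
              nrow(x$assignment), x$k, x$tot_withinss, x$iterations))
  print(table(x$assignment$cluster))
  invisible(x)
}
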