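#' Parameters for the single-cell count simulator
#'
#' Emulates the droplet scRNA-seq stage of the study: roughly 3000
#' reporter-positive cells at the latest stage, falling into eight
#' subpopulations arranged along a differentiation pseudotime (three early
#' clusters, four intermediate, one late terminal cluster). Counts are
#' Poisson with cluster-specific log-mean vectors: each cluster up-shifts
#' its private marker genes by `separation` log-expression sd units.
#' Mitochondrial genes carry the feature prefix `mt-`; a small fraction of
#' cells is planted with a high mitochondrial load, and doublets are sums
#' of two random singlet profiles.
#'
#' @param n_cells,n_genes Matrix dimensions (defaults 3000 x 2000).
#' @param k_clusters Number of planted subpopulations (default 8, labelled
#'   0..k-1).
#' @param separation Marker log-mean shift in log-expression sd units.
#' @param n_markers Private marker genes per cluster.
#' @param n_mito Number of `mt-` prefixed genes.
#' @param base_log_mean,base_log_sd Per-gene baseline log-mean
#'   distribution.
#' @param libsize_log_sd Per-cell library-size log-normal sd.
#' @param mito_scale Baseline log-mean shift of mitochondrial genes.
#' @param frac_high_mito Fraction of cells planted with ~10x mitochondrial
#'   load.
#' @param doublet_fraction Fraction of cells that are doublets.
#' @param pseudotime_rule Named vector mapping cluster label ->
#'   mean pseudotime in `[0, 1]`; the default realises the early (clusters
#'   1, 5, 7) / intermediate (0, 3, 4, 6) / late (2) progression.
#' @param pseudotime_sd Per-cell jitter around the cluster mean.
#' @param feature_names Optional explicit feature names (length `n_genes`;
#'   `mt-` prefixed names are treated as mitochondrial). Lets the
#'   single-cell universe share gene ids with a bulk simulation.
#' @param marker_pools Optional named list (cluster label -> character
#'   vector of feature names) restricting where that cluster's markers are
#'   drawn from; clusters without an entry draw from the remaining pool.
#'   This is how joint bulk/single-cell structure is planted.
#' @return Named parameter list for [simulate_sc()].
#' @export
sc_sim_params <- function(n_cells = 3000L, n_genes = 2000L, k_clusters = 8L,
                          separation = 5, n_markers = 25L, n_mito = 10L,
                          base_log_mean = -1, base_log_sd = 1,
                          libsize_log_sd = 0.3, mito_scale = 2,
                          frac_high_mito = 0.02, doublet_fraction = 0.03,
                          pseudotime_rule = c(`5` = 0.05, `1` = 0.15, `7` = 0.25,
                                              `0` = 0.40, `3` = 0.50, `4` = 0.60,
                                              `6` = 0.70, `2` = 0.92),
                          pseudotime_sd = 0.03,
                          feature_names = NULL, marker_pools = NULL) {
  p <- as.list(environment())
  p$n_cells <- as.integer(n_cells); p$n_genes <- as.integer(n_genes)
  p$k_clusters <- as.integer(k_clusters)
  validate_sc_sim_params(p)
}

validate_sc_sim_params <- function(p) {
  if (p$k_clusters < 2L) abort("k_clusters must be >= 2.")
  if (p$n_cells < p$k_clusters) abort("n_cells must be >= k_clusters.")
  if (p$doublet_fraction < 0 || p$doublet_fraction > 1 ||
      p$frac_high_mito < 0 || p$frac_high_mito > 1) {
    abort("fractions must lie in [0, 1].")
  }
  if (length(p$pseudotime_rule) != p$k_clusters) {
    p$pseudotime_rule <- setNames(
      seq(0.05, 0.95, length.out = p$k_clusters),
      as.character(seq_len(p$k_clusters) - 1L))
  }
  if (p$k_clusters * p$n_markers + p$n_mito > p$n_genes) {
    abort("n_genes too small for the requested markers and mito genes.")
  }
  p
}

#' Simulate a single-cell UMI count matrix with planted structure
#'
#' @param params Parameter list from [sc_sim_params()].
#' @param seed Integer seed.
#' @return A list: `counts` (sparse genes x cells integer matrix with
#'   barcode column names and feature row names), `features`, `barcodes`,
#'   and `truth` — a per-cell tibble with `barcode`, planted `cluster`
#'   (character label `0..k-1`), `pseudotime`, `is_doublet`,
#'   `high_mito`.
#' @export
simulate_sc <- function(params, seed = 1L) {
  params <- validate_sc_sim_params(params)
  set.seed(seed)
  n_g <- params$n_genes; n_c <- params$n_cells; k <- params$k_clusters
  features <- params$feature_names %||%
    c(sprintf("mt-sim%02d", seq_len(params$n_mito)),
      sprintf("sgene%05d", seq_len(n_g - params$n_mito)))
  if (length(features) != n_g) abort("feature_names must have length n_genes.")
  mito <- which(startsWith(features, "mt-"))
  base <- rnorm(n_g, params$base_log_mean, params$base_log_sd)
  base[mito] <- params$base_log_mean + params$mito_scale

  cluster_labels <- as.character(seq_len(k) - 1L)
  remaining <- setdiff(seq_len(n_g), mito)
  markers <- vector("list", k)
  # clusters with an explicit marker pool pick first so random clusters
  # cannot exhaust their candidates
  pooled_first <- order(!cluster_labels %in% names(params$marker_pools))
  for (c_i in pooled_first) {
    pool <- remaining
    wanted <- params$marker_pools[[cluster_labels[c_i]]]
    if (!is.null(wanted)) {
      pool <- intersect(remaining, match(wanted, features))
      if (length(pool) < params$n_markers) {
        abort(paste0("marker_pools for cluster ", cluster_labels[c_i],
                     " has fewer than n_markers available genes."))
      }
    }
    markers[[c_i]] <- sample(pool, params$n_markers)
    remaining <- setdiff(remaining, markers[[c_i]])
  }
  logmu <- matrix(base, n_g, k)
  for (c_i in seq_len(k)) {
    logmu[markers[[c_i]], c_i] <- logmu[markers[[c_i]], c_i] +
      params$separation * params$base_log_sd
  }

  n_doublet <- round(params$doublet_fraction * n_c)
  n_singlet <- n_c - n_doublet
  cl <- sample(cluster_labels, n_singlet, replace = TRUE)
  sizef <- exp(rnorm(n_singlet, 0, params$libsize_log_sd))
  high_mito <- runif(n_singlet) < params$frac_high_mito
  mito_boost <- if_else(high_mito, 10, 1)

  draw_cell <- function(i) {
    mu <- exp(logmu[, match(cl[i], cluster_labels)]) * sizef[i]
    mu[mito] <- mu[mito] * mito_boost[i]
    rpois(n_g, mu)
  }
  counts <- vapply(seq_len(n_singlet), draw_cell, integer(n_g))

  is_doublet <- c(rep(FALSE, n_singlet), rep(TRUE, n_doublet))
  if (n_doublet > 0L) {
    a <- sample.int(n_singlet, n_doublet, replace = TRUE)
    b <- sample.int(n_singlet, n_doublet, replace = TRUE)
    counts <- cbind(counts, counts[, a, drop = FALSE] + counts[, b, drop = FALSE])
    cl <- c(cl, cl[a])
    high_mito <- c(high_mito, high_mito[a] | high_mito[b])
  }

  pt <- pmin(1, pmax(0, params$pseudotime_rule[cl] +
                       rnorm(length(cl), 0, params$pseudotime_sd)))
  barcodes <- sprintf("cell%05d", seq_len(ncol(counts)))
  dimnames(counts) <- list(features, barcodes)
  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    features = features,
    barcodes = barcodes,
    truth = tibble(barcode = barcodes, cluster = cl,
                   pseudotime = unname(pt), is_doublet = is_doublet,
                   high_mito = high_mito)
  )
}

#' Write / read a single-cell count matrix as MTX plus side files
#'
#' The on-disk layout follows the droplet convention: `matrix.mtx`
#' (genes x cells, MatrixMarket), `features.tsv` and `barcodes.tsv`, plus
#' an optional `pseudotime.tsv` (barcode, value).
#'
#' @param sc A list with `counts`, `features`, `barcodes` (as returned by
#'   [simulate_sc()]); `truth$pseudotime` is written when present.
#' @param dir Output directory (created if needed).
#' @return `read_sc_counts()` returns a list with `counts`, `features`,
#'   `barcodes` and, when present on disk, `pseudotime`.
#' @export
write_sc_counts <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sc$counts, file.path(dir, "matrix.mtx"))
  readr::write_lines(sc$features, file.path(dir, "features.tsv"))
  readr::write_lines(sc$barcodes, file.path(dir, "barcodes.tsv"))
  if (!is.null(sc$truth) && "pseudotime" %in% names(sc$truth)) {
    readr::write_tsv(sc$truth[, c("barcode", "pseudotime")],
                     file.path(dir, "pseudotime.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sc_counts
#' @export
read_sc_counts <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  features <- readr::read_lines(file.path(dir, "features.tsv"), progress = FALSE)
  barcodes <- readr::read_lines(file.path(dir, "barcodes.tsv"), progress = FALSE)
  dimnames(counts) <- list(features, barcodes)
  out <- list(counts = counts, features = features, barcodes = barcodes)
  pt_path <- file.path(dir, "pseudotime.tsv")
  if (file.exists(pt_path)) {
    out$pseudotime <- readr::read_tsv(pt_path, show_col_types = FALSE, progress = FALSE)
  }
  out
}
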