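#' Per-cell QC metrics
#'
#' @param counts Sparse or dense genes x cells count matrix with feature
#'   row names; mitochondrial genes are those whose feature name starts
#'   with `mt-`.
#' @return A tibble `barcode`, `total_counts`, `n_genes`,
#'   `mito_fraction`.
#' @export
cell_qc_metrics <- function(counts) {
  mito <- startsWith(rownames(counts), "mt-")
  totals <- Matrix::colSums(counts)
  tibble(
    barcode = colnames(counts) %||% as.character(seq_len(ncol(counts))),
    total_counts = as.numeric(totals),
    n_genes = as.integer(Matrix::colSums(counts > 0)),
    mito_fraction = if_else(totals > 0,
                            as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) /
                              as.numeric(totals),
                            0)
  )
}

#' Filter cells and drop mitochondrial genes
#'
#' Removes cells whose detected-gene count falls outside
#' `[min_genes, max_genes]` (a multiplet gate at the top end) or whose
#' mitochondrial fraction exceeds `max_mito_fraction`, then excludes the
#' `mt-` features from the downstream gene space. Idempotent.
#'
#' @param counts Genes x cells count matrix.
#' @param min_genes,max_genes Detected-gene bounds (inclusive).
#' @param max_mito_fraction Mitochondrial-fraction ceiling (inclusive).
#' @return A list: `counts` (filtered matrix, mito genes removed) and
#'   `removed`, a tibble `barcode`, `reason` logging discarded cells.
#' @export
qc_filter <- function(counts, min_genes = 500L, max_genes = 6000L,
                      max_mito_fraction = 0.1) {
  if (min_genes < 0 || max_genes <= min_genes) {
    abort("Need 0 <= min_genes < max_genes.")
  }
  qc <- cell_qc_metrics(counts)
  reason <- dplyr::case_when(
    qc$mito_fraction > max_mito_fraction ~ "high_mito",
    qc$n_genes < min_genes ~ "few_genes",
    qc$n_genes > max_genes ~ "many_genes",
    .default = NA_character_
  )
  keep <- is.na(reason)
  if (!any(keep)) abort("QC removed every cell; thresholds are inconsistent with the data.")
  mito <- startsWith(rownames(counts), "mt-")
  list(
    counts = counts[!mito, keep, drop = FALSE],
    removed = tibble(barcode = qc$barcode[!keep], reason = reason[!keep])
  )
}

#' Library-size log-normalization
#'
#' `log(1 + count / cell_total * scale_factor)`; zeros stay zero and the
#' result stays sparse.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Target library size (default 1e4).
#' @return A sparse genes x cells matrix of normalized values.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  if (scale_factor <= 0) abort("scale_factor must be > 0.")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) abort("Cell with zero total counts; filter it first.")
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

#' Highly variable gene selection by binned dispersion
#'
#' Per-gene dispersion (variance / mean of the normalized values; 0 where
#' the mean is 0) is z-scored within 20 equal-frequency bins of the gene
#' mean, and the top `n_top` genes by z-score are returned — the classic
#' mean-dispersion HVG strategy.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param n_top Number of genes to select.
#' @param n_bins Number of mean-expression bins.
#' @return Character vector of `n_top` feature names, ordered by
#'   decreasing dispersion z-score.
#' @export
select_hvg <- function(normalized, n_top = 2000L, n_bins = 20L) {
  n_genes <- nrow(normalized)
  if (n_top > n_genes) abort("n_top exceeds the number of genes.")
  mu <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  v <- pmax(0, (ex2 - mu^2) * ncol(normalized) / max(1, ncol(normalized) - 1))
  disp <- if_else(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, n_genes %/% 10L))
  bin <- dplyr::ntile(mu, n_bins)
  z <- disp
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[disp == 0] <- -Inf  # invariant genes are never variable
  names(z) <- rownames(normalized) %||% as.character(seq_len(n_genes))
  names(sort(z, decreasing = TRUE))[seq_len(n_top)]
}

#' PCA cell embedding
#'
#' Centred (not scaled) PCA of cells over the selected genes, with each
#' component's sign fixed so its largest-magnitude gene loading is
#' positive — making the embedding deterministic across platforms.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param genes Optional feature subset (e.g. from [select_hvg()]).
#' @param n_pcs Number of components.
#' @return Cells x `n_pcs` numeric matrix with barcode row names and an
#'   attribute `sdev` of component standard deviations.
#' @export
pca_embed <- function(normalized, genes = NULL, n_pcs = 20L) {
  x <- if (is.null(genes)) normalized else normalized[genes, , drop = FALSE]
  m <- t(as.matrix(x))  # cells x genes
  if (n_pcs < 1L || n_pcs > min(dim(m))) {
    abort("n_pcs must lie in [1, min(cells, genes)].")
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- fit$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 1)
  emb <- sweep(fit$x[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  rownames(emb) <- colnames(x)
  attr(emb, "sdev") <- fit$sdev[seq_len(n_pcs)]
  emb
}

#' Per-cluster marker genes by fold change and rank-sum test
#'
#' For every gene and cluster: log2 fold change of the pseudocounted
#' cluster mean over the rest mean, and a two-sided Wilcoxon rank-sum
#' p-value (normal approximation with tie correction) with
#' Benjamini-Hochberg FDR across all gene x cluster tests. Singleton
#' clusters trigger a warning and get fold changes only.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param clusters Tibble `barcode`, `cluster` (e.g.
#'   `kmeans_cluster()$assignment`).
#' @param pseudocount Added to both means in the fold change.
#' @param max_fdr FDR gate for the ranked marker lists.
#' @return A tibble `cluster`, `gene_id`, `log2_fc`, `p_value`, `fdr`,
#'   `rank` (rank by fold change among FDR-passing genes; NA otherwise),
#'   sorted within cluster.
#' @export
cluster_markers <- function(normalized, clusters, pseudocount = 0.01,
                            max_fdr = 0.05) {
  cl <- clusters$cluster[match(colnames(normalized), clusters$barcode)]
  if (any(is.na(cl))) abort("Every cell must carry a cluster label.")
  levels <- sort(unique(cl))
  if (length(levels) < 2L) abort("Need >= 2 clusters for marker detection.")
  x <- as.matrix(normalized)
  n <- ncol(x)
  # rank every gene once across cells; rank-sums per cluster are then
  # column sums over the membership indicator
  ranks <- t(apply(x, 1, rank))
  tie_term <- apply(x, 1, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    in_c <- cl == levels[i]
    n1 <- sum(in_c); n2 <- n - n1
    mean_in <- rowMeans(x[, in_c, drop = FALSE])
    mean_out <- rowMeans(x[, !in_c, drop = FALSE])
    lfc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
    if (n1 < 2L) {
      warn(paste0("Cluster ", levels[i], " is a singleton; fold change only."))
      p <- rep(NA_real_, nrow(x))
    } else {
      w <- rowSums(ranks[, in_c, drop = FALSE]) - n1 * (n1 + 1) / 2
      mu_w <- n1 * n2 / 2
      sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      z <- (w - mu_w) / sqrt(pmax(sigma2, .Machine$double.eps))
      p <- 2 * stats::pnorm(-abs(z))
    }
    out[[i]] <- tibble(cluster = levels[i],
                       gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                       log2_fc = unname(lfc), p_value = unname(p))
  }
  res <- bind_rows(out)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res |>
    group_by(.data$cluster) |>
    arrange(dplyr::desc(.data$log2_fc), .by_group = TRUE) |>
    mutate(rank = {
      ok <- !is.na(.data$fdr) & .data$fdr < max_fdr
      r <- rep(NA_integer_, dplyr::n()); r[ok] <- seq_len(sum(ok)); r
    }) |>
    ungroup()
}

#' Gene filter for trajectory reconstruction
#'
#' The input-gene gate of the pseudotime stage: genes detected in strictly
#' more than `min_cells` cells whose mean expression is strictly above
#' `min_mean`.
#'
#' @param counts Genes x cells count matrix.
#' @param min_cells,min_mean Strict thresholds (defaults 10 and 1).
#' @return Character vector of passing feature names.
#' @export
trajectory_gene_filter <- function(counts, min_cells = 10L, min_mean = 1) {
  det <- Matrix::rowSums(counts > 0)
  mu <- Matrix::rowMeans(counts)
  feats <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  sort(feats[det > min_cells & mu > min_mean])
}

#' Top-expressed genes of each cluster
#'
#' Ranks genes by within-cluster mean normalized expression and returns
#' the top `ceiling(fraction * n_expressed)` per cluster, where expressed
#' means a nonzero cluster mean.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param clusters Tibble `barcode`, `cluster`.
#' @param fraction Fraction in (0, 1] (default 0.2).
#' @return Named list (by cluster) of character vectors of feature names.
#' @export
top_fraction_genes <- function(normalized, clusters, fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1].")
  cl <- clusters$cluster[match(colnames(normalized), clusters$barcode)]
  feats <- rownames(normalized) %||% as.character(seq_len(nrow(normalized)))
  out <- list()
  for (lev in sort(unique(cl))) {
    mu <- Matrix::rowMeans(normalized[, cl == lev, drop = FALSE])
    expressed <- which(mu > 0)
    n_take <- ceiling(fraction * length(expressed))
    ord <- expressed[order(mu[expressed], decreasing = TRUE)]
    out[[lev]] <- feats[ord[seq_len(n_take)]]
  }
  out
}

#' Group clusters into pseudotime states
#'
#' Computes the mean pseudotime of each cluster's cells and cuts the
#' cluster means at two boundaries (default: tertiles of the cluster
#' means) into `early`, `intermediate` and `late` states — the
#' C157/C0346/C2-style grouping of subpopulations along the
#' differentiation axis. An explicit `cluster_map` overrides the
#' data-driven cut.
#'
#' @param clusters Tibble `barcode`, `cluster`.
#' @param pseudotime Tibble `barcode`, `pseudotime` (values in [0, 1]).
#' @param boundaries Two strictly increasing cut points on cluster-mean
#'   pseudotime, or `NULL` for tertiles.
#' @param cluster_map Optional named character vector cluster -> state.
#' @return A tibble `cluster`, `mean_pseudotime`, `state`.
#' @export
assign_state_groups <- function(clusters, pseudotime, boundaries = NULL,
                                cluster_map = NULL) {
  df <- clusters |>
    inner_join(pseudotime, by = "barcode")
  if (nrow(df) < nrow(clusters)) {
    abort("Pseudotime must cover every clustered cell.")
  }
  means <- df |>
    group_by(.data$cluster) |>
    summarise(mean_pseudotime = mean(.data$pseudotime), .groups = "drop")
  if (!is.null(cluster_map)) {
    means$state <- unname(cluster_map[means$cluster])
    if (any(is.na(means$state))) abort("cluster_map must cover every cluster.")
    return(means)
  }
  if (is.null(boundaries)) {
    boundaries <- unname(quantile(means$mean_pseudotime, c(1 / 3, 2 / 3)))
  }
  if (length(boundaries) != 2L || diff(boundaries) <= 0) {
    abort("boundaries must be two strictly increasing values.")
  }
  means |>
    mutate(state = dplyr::case_when(
      .data$mean_pseudotime <= boundaries[1] ~ "early",
      .data$mean_pseudotime <= boundaries[2] ~ "intermediate",
      .default = "late"))
}
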