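toy_counts <- function() {
  # 4 genes (one mitochondrial) x 4 cells with hand-set structure
  m <- matrix(c(
    10, 0, 2, 1,    # mt-gene
    5, 5, 5, 5,
    0, 8, 0, 0,
    1, 2, 3, 4), nrow = 4, byrow = TRUE,
    dimnames = list(c("mt-a", "g1", "g2", "g3"),
                    c("c1", "c2", "c3", "c4")))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("QC metrics and filtering remove high-mito and out-of-range cells", {
  m <- toy_counts()
  qc <- cell_qc_metrics(m)
  expect_equal(qc$total_counts, c(16, 15, 10, 10))
  expect_equal(qc$mito_fraction, c(10 / 16, 0, 2 / 10, 1 / 10))
  out <- qc_filter(m, min_genes = 0L, max_genes = 10L, max_mito_fraction = 0.25)
  expect_equal(out$removed$barcode, c("c1"))
  expect_equal(out$removed$reason, "high_mito")
  expect_false("mt-a" %in% rownames(out$counts))
  # identity thresholds keep everything (but still drop mito features)
  all_kept <- qc_filter(m, min_genes = 0L, max_genes = 1e6L, max_mito_fraction = 1)
  expect_equal(ncol(all_kept$counts), 4)
  # idempotence
  again <- qc_filter(out$counts, min_genes = 0L, max_genes = 10L,
                     max_mito_fraction = 0.25)
  expect_equal(as.matrix(again$counts), as.matrix(out$counts))
  expect_equal(nrow(again$removed), 0)
  expect_error(qc_filter(m, min_genes = 4L, max_genes = 5L,
                         max_mito_fraction = 0), "every cell")
})

test_that("log-normalization matches its defining formula", {
  m <- toy_counts()
  norm <- normalize_log(m, scale_factor = 100)
  want <- log1p(sweep(as.matrix(m), 2, Matrix::colSums(m), "/") * 100)
  expect_equal(as.matrix(norm), want)
  expect_equal(norm["g2", "c1"], 0)  # zero stays zero
  # a uniform cell normalizes to uniform values
  u <- methods::as(Matrix::Matrix(matrix(3, 4, 2,
        dimnames = list(paste0("g", 1:4), c("a", "b"))), sparse = TRUE),
        "CsparseMatrix")
  nu <- normalize_log(u, 100)
  expect_equal(length(unique(round(nu@x, 12))), 1L)
  zero <- m; zero[, 2] <- 0
  expect_error(normalize_log(zero), "zero total")
})

test_that("HVG selection favours planted variance and ignores constant genes", {
  set.seed(3)
  n_cells <- 60
  base <- matrix(rpois(50 * n_cells, 5), 50, n_cells)
  hv <- ifelse(runif(n_cells) < 0.5, 0, 40)  # one bimodal gene
  m <- rbind(base, hv, matrix(4, 1, n_cells))
  rownames(m) <- c(sprintf("g%02d", 1:50), "planted", "constant")
  colnames(m) <- sprintf("c%02d", 1:n_cells)
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  norm <- normalize_log(sm)
  got <- select_hvg(norm, n_top = 5)
  expect_equal(got[1], "planted")
  expect_false("constant" %in% select_hvg(norm, n_top = 20))
  expect_length(select_hvg(norm, 10), 10)
  expect_error(select_hvg(norm, 1000), "n_top")
})

test_that("PCA embedding matches an independent eigendecomposition", {
  set.seed(8)
  m <- matrix(rnorm(200), nrow = 10)  # 10 genes x 20 cells
  dimnames(m) <- list(paste0("g", 1:10), paste0("c", 1:20))
  norm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  emb <- pca_embed(norm, n_pcs = 5)
  cells <- t(m)
  centred <- scale(cells, center = TRUE, scale = FALSE)
  eig <- eigen(cov(centred))
  proj <- centred %*% eig$vectors[, 1:5]
  for (j in 1:5) {
    expect_equal(abs(emb[, j]), abs(proj[, j]), tolerance = 1e-8)
  }
  v <- apply(emb, 2, var)
  expect_true(all(diff(v) <= 1e-8))
  # exact rank-1 data: first component holds all the variance
  r1 <- outer(1:6, seq(0.5, 2, length.out = 8))
  dimnames(r1) <- list(paste0("g", 1:6), paste0("c", 1:8))
  e1 <- pca_embed(methods::as(Matrix::Matrix(r1, sparse = TRUE), "CsparseMatrix"),
                  n_pcs = 3)
  sdev <- attr(e1, "sdev")
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.999999)
  expect_error(pca_embed(norm, n_pcs = 100), "n_pcs")
})

test_that("k-means recovers planted structure, is deterministic and monotone", {
  set.seed(2)
  centres <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  x <- centres[rep(1:3, each = 50), ] + matrix(rnorm(300, sd = 0.5), 150, 2)
  rownames(x) <- sprintf("c%03d", 1:150)
  km <- kmeans_cluster(x, k = 3, seed = 9)
  expect_equal(adjusted_rand_index(km$assignment$cluster, rep(1:3, each = 50)), 1)
  expect_identical(km$assignment, kmeans_cluster(x, k = 3, seed = 9)$assignment)
  expect_true(all(diff(km$objective_trace) <= 1e-8))
  # independent implementation agrees on the objective at the optimum
  ref <- stats::kmeans(x, centers = 3, nstart = 10)
  expect_equal(km$tot_withinss, ref$tot.withinss, tolerance = 1e-6)
  # mclust cross-checks our adjusted Rand index
  skip_if_not_installed("mclust")
  lab <- sample(1:3, 150, replace = TRUE)
  expect_equal(adjusted_rand_index(km$assignment$cluster, lab),
               mclust::adjustedRandIndex(km$assignment$cluster, lab))
  # k = n gives a zero objective
  small <- x[1:5, ]
  expect_equal(kmeans_cluster(small, k = 5, seed = 1)$tot_withinss, 0)
  expect_error(kmeans_cluster(small, k = 6), "exceed")
})

test_that("marker detection finds exclusive genes and matches wilcox.test", {
  set.seed(4)
  n <- 40
  cl <- rep(c("0", "1"), each = n / 2)
  m <- matrix(rpois(6 * n, 3), 6, n)
  m[1, cl == "0"] <- m[1, cl == "0"] + 30  # exclusive-ish marker of cluster 0
  dimnames(m) <- list(paste0("g", 1:6), sprintf("c%02d", 1:n))
  norm <- normalize_log(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                    "CsparseMatrix"))
  clusters <- tibble::tibble(barcode = colnames(m), cluster = cl)
  mk <- cluster_markers(norm, clusters)
  top0 <- mk |> dplyr::filter(cluster == "0", rank == 1)
  expect_equal(top0$gene_id, "g1")
  # rank-sum p agrees with wilcox.test's normal approximation
  ref <- wilcox.test(as.matrix(norm)["g1", cl == "0"],
                     as.matrix(norm)["g1", cl == "1"],
                     exact = FALSE, correct = FALSE)
  got <- mk |> dplyr::filter(cluster == "0", gene_id == "g1")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  # relabelling clusters permutes the output rows, not the numbers
  swapped <- tibble::tibble(barcode = colnames(m),
                            cluster = ifelse(cl == "0", "1", "0"))
  mk2 <- cluster_markers(norm, swapped)
  expect_equal(mk |> dplyr::filter(cluster == "0") |> dplyr::pull(log2_fc),
               mk2 |> dplyr::filter(cluster == "1") |> dplyr::pull(log2_fc))
})

test_that("the trajectory input-gene filter applies strict thresholds", {
  m <- matrix(0, 3, 20, dimnames = list(c("in11", "out10", "low"), NULL))
  m["in11", 1:11] <- 2  # 11 cells, mean 22/20 = 1.1 > 1
  m["out10", 1:10] <- 3  # 10 cells: excluded (strict >)
  m["low", 1:15] <- 1    # mean 0.75: excluded
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  expect_equal(trajectory_gene_filter(sm), "in11")
  m2 <- matrix(1, 1, 20, dimnames = list("meanone", NULL))  # mean exactly 1
  expect_length(trajectory_gene_filter(
    methods::as(Matrix::Matrix(m2, sparse = TRUE), "CsparseMatrix")), 0)
})

test_that("top-fraction gene sets use ceiling over expressed genes", {
  n_cells <- 10
  m <- matrix(0, 12, n_cells,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("c%02d", 1:n_cells)))
  m[1:10, ] <- matrix(rep(10:1, n_cells), 10)  # gene g01 highest ... g10 lowest
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  clusters <- tibble::tibble(barcode = colnames(m), cluster = "0")
  # 10 expressed genes, fraction 0.2 -> 2
  expect_equal(top_fraction_genes(sm, clusters, 0.2)[["0"]], c("g01", "g02"))
  m11 <- m; m11[11, ] <- 0.5  # 11 expressed genes -> ceiling(2.2) = 3
  sm11 <- methods::as(Matrix::Matrix(m11, sparse = TRUE), "CsparseMatrix")
  expect_length(top_fraction_genes(sm11, clusters, 0.2)[["0"]], 3)
  expect_length(top_fraction_genes(sm, clusters, 1)[["0"]], 10)
  expect_error(top_fraction_genes(sm, clusters, 0), "fraction")
})

test_that("state groups cut cluster-mean pseudotime at the boundaries", {
  clusters <- tibble::tibble(barcode = sprintf("c%02d", 1:9),
                             cluster = rep(c("0", "1", "2"), each = 3))
  pt <- tibble::tibble(barcode = clusters$barcode,
                       pseudotime = c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5, 0.9, 0.9, 0.9))
  sg <- assign_state_groups(clusters, pt, boundaries = c(0.3, 0.7))
  expect_equal(sg$state, c("early", "intermediate", "late"))
  ov <- assign_state_groups(clusters, pt,
                            cluster_map = c(`0` = "late", `1` = "late", `2` = "early"))
  expect_equal(ov$state, c("late", "late", "early"))
  expect_error(assign_state_groups(clusters, pt, boundaries = c(0.7, 0.3)),
               "increasing")
  expect_error(assign_state_groups(clusters, pt[1:5, ]), "cover")
})

test_that("set overlaps and TF target distributions count correctly", {
  ov <- set_overlap_stats(c("a", "b", "c", "d"), c("b", "d", "e"))
  expect_equal(ov$n_intersect, 2)
  expect_equal(ov$pct_of_reference, 50)
  expect_equal(set_overlap_stats(c("a", "b"), character(0))$pct_of_reference, 0)
  expect_equal(set_overlap_stats(c("a", "b"), c("a", "b", "c"))$pct_of_reference, 100)
  expect_error(set_overlap_stats(character(0), "a"), "Empty")

  states <- list(early = c("g1", "g2"), mid = c("g3", "g4"), late = "g5")
  tt <- tf_target_distribution(paste0("g", 1:5), states)
  expect_equal(tt$n_targets, c(2, 2, 1))
  expect_equal(tf_target_distribution(character(0), states)$n_targets, c(0, 0, 0))
  expect_lte(sum(tt$n_targets), 5)
  expect_error(tf_target_distribution("g1", list(a = "g1", b = "g1")), "disjoint")
})

test_that("doublets inflate gene counts and are removed by the upper QC gate", {
  p <- sc_sim_params(n_cells = 400, n_genes = 600, doublet_fraction = 0.1,
                     frac_high_mito = 0)
  sc <- simulate_sc(p, seed = 13)
  qc <- cell_qc_metrics(sc$counts)
  singlet_p99 <- quantile(qc$n_genes[!sc$truth$is_doublet], 0.99)
  out <- qc_filter(sc$counts, min_genes = 0L,
                   max_genes = as.integer(singlet_p99),
                   max_mito_fraction = 1)
  removed_doublet <- sc$truth$is_doublet[match(out$removed$barcode, sc$truth$barcode)]
  doublet_rate <- sum(removed_doublet) / sum(sc$truth$is_doublet)
  singlet_rate <- sum(!removed_doublet) / sum(!sc$truth$is_doublet)
  # the gate removes doublets far more often than singlets
  expect_gt(doublet_rate, 0.3)
  expect_gt(doublet_rate, 3 * singlet_rate)
})
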