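test_that("simulated annotations are disjoint, deterministic, and fail when infeasible", {
  ann <- simulate_annotation(40, c(chrA = 4e6), seed = 5)
  expect_equal(nrow(ann), 40)
  by_chrom <- split(ann, ann$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_true(all(purrr::map_int(ann$exons, nrow) >= 1L))
  expect_identical(ann, simulate_annotation(40, c(chrA = 4e6), seed = 5))
  expect_error(simulate_annotation(1000, c(chrA = 1e6), seed = 1), "overlap")
})

test_that("planted class frequencies follow the class prior", {
  ann <- simulate_annotation(1000, c(chrA = 2e7, chrB = 2e7), seed = 2)
  probs <- setNames(rep(1 / 27, 27), enumerate_class_space()$class)
  bk <- simulate_bulk(bulk_sim_params(class_probabilities = probs), ann, seed = 2)
  counts <- table(factor(bk$truth$class, levels = names(probs)))
  # each count is Binomial(1000, 1/27); check all lie in the 99.9% interval
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 1000, 1 / 27)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
  # goodness of fit as a second, global look
  expect_gt(chisq.test(counts, p = probs)$p.value, 1e-4)
})

test_that("zero replicate noise collapses replicates and yields exact truth recovery", {
  ann <- simulate_annotation(300, c(chrA = 2e7), seed = 3)
  bk <- simulate_bulk(bulk_sim_params(replicate_log_sd = 0), ann, seed = 3)
  expect_equal(bk$table$pos_E11.5_1, bk$table$pos_E11.5_2)
  expect_equal(bk$table$neg_E15.5_1, bk$table$neg_E15.5_2)
  ratios <- compute_stage_ratio(bk$table)
  cls <- classify_temporal(ratios)
  truth <- bk$truth[match(cls$gene_id, bk$truth$gene_id), ]
  expect_equal(cls$class, truth$class)
})

test_that("bulk truth flags are internally consistent with the generating rules", {
  ann <- simulate_annotation(400, c(chrA = 2e7), seed = 7)
  bk <- simulate_bulk(bulk_sim_params(), ann, seed = 7)
  tr <- bk$truth
  # a CR-specific gene is planted up at all stages
  expect_true(all(tr$class[tr$cr_specific] == "E11up-E13up-E15up"))
  pos_cols <- paste0("pos_mean_", stage_levels())
  expect_true(all(as.matrix(tr[tr$cr_specific, pos_cols]) >= 5))
  expect_true(all(tr$neg_mean[tr$layer1] <= 15))
  expect_true(all(tr$layer1[tr$layer1] & tr$cr_specific[tr$layer1]))
  # planted DE statistics respect their gates
  expect_true(all(bk$table$de_fdr[tr$de] < 0.05))
  expect_true(all(bk$table$de_p[tr$de] < 0.01))
  expect_true(all(bk$table$de_fdr >= bk$table$de_p))
})

test_that("invalid ratio ranges are rejected", {
  expect_error(bulk_sim_params(ratio_ranges = list(up = c(1.5, 6),
                                                   unchanged = c(1.05, 1.9),
                                                   down = c(0.1, 0.85))),
               "ratio_ranges")
})

test_that("emitted peaks reproduce planted TSS states exactly at zero background", {
  ann <- simulate_annotation(120, c(chrA = 2e7), seed = 11)
  bk <- simulate_bulk(bulk_sim_params(), ann, seed = 11)
  pk <- simulate_peaks(ann, bk$truth, chrom_sizes = c(chrA = 2e7),
                       background_rate = 0, seed = 11)
  bindings <- assign_tss_binding(pk$peaks, ann)
  states <- tss_states(bindings)
  truth_long <- pk$truth |>
    dplyr::select(gene_id, dplyr::starts_with("state_")) |>
    tidyr::pivot_longer(-gene_id, names_to = "condition",
                        values_to = "true_state", names_prefix = "state_")
  j <- dplyr::inner_join(states, truth_long, by = c("gene_id", "condition"))
  expect_equal(nrow(j), 120 * 4)
  expect_equal(j$state, j$true_state)
  # a poised gene carries both marks over its TSS window
  poised <- j$gene_id[j$condition == "pos_E11.5" & j$true_state == "poised"][1]
  if (!is.na(poised)) {
    b <- bindings[bindings$gene_id == poised & bindings$sample == "pos_E11.5_1", ]
    expect_true(all(b$tss_bound))
  }
  # every realized distal flag is recovered as distal binding
  distal_truth <- pk$truth |>
    dplyr::select(gene_id, dplyr::starts_with("distal_")) |>
    tidyr::pivot_longer(-gene_id, names_to = "key", values_to = "flag") |>
    dplyr::filter(flag)
  key_of <- paste("distal", bindings$mark, sub("_[0-9]+$", "", bindings$sample),
                  sep = "_")
  hit <- dplyr::inner_join(
    dplyr::mutate(bindings, key = key_of), distal_truth,
    by = c("gene_id", "key"))
  expect_true(all(hit$distal_bound))
})

test_that("peak generator validates its windows and responds to background", {
  ann <- simulate_annotation(20, c(chrA = 5e6), seed = 1)
  bk <- simulate_bulk(bulk_sim_params(), ann, seed = 1)
  expect_error(simulate_peaks(ann, bk$truth, tss_window = 0), "tss_window")
  with_bg <- simulate_peaks(ann, bk$truth, chrom_sizes = c(chrA = 5e6),
                            background_rate = 20, seed = 2)
  no_bg <- simulate_peaks(ann, bk$truth, chrom_sizes = c(chrA = 5e6),
                          background_rate = 0, seed = 2)
  expect_gt(nrow(with_bg$peaks), nrow(no_bg$peaks))
})

test_that("single-cell simulation is deterministic with controllable artefacts", {
  p <- sc_sim_params(n_cells = 150, n_genes = 300, doublet_fraction = 0)
  a <- simulate_sc(p, seed = 4)
  b <- simulate_sc(p, seed = 4)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_false(any(a$truth$is_doublet))
  expect_true(all(a$counts@x == round(a$counts@x)))
  expect_error(sc_sim_params(n_cells = 4, k_clusters = 8), "n_cells")
})

test_that("well-separated planted clusters are exactly recoverable", {
  p <- sc_sim_params(n_cells = 300, n_genes = 400, k_clusters = 3,
                     separation = 10, doublet_fraction = 0, frac_high_mito = 0)
  sc <- simulate_sc(p, seed = 6)
  norm <- normalize_log(sc$counts)
  emb <- pca_embed(norm, select_hvg(norm, 200), n_pcs = 10)
  km <- kmeans_cluster(emb, k = 3, seed = 6)
  truth <- sc$truth$cluster[match(km$assignment$barcode, sc$truth$barcode)]
  expect_equal(adjusted_rand_index(km$assignment$cluster, truth), 1)
})

test_that("class recovery degrades monotonically with replicate noise", {
  ann <- simulate_annotation(250, c(chrA = 2e7), seed = 9)
  recovery_at <- function(sd) {
    mean(vapply(1:3, function(s) {
      bk <- simulate_bulk(bulk_sim_params(replicate_log_sd = sd), ann, seed = s)
      cls <- classify_temporal(compute_stage_ratio(bk$table))
      mean(cls$class == bk$truth$class[match(cls$gene_id, bk$truth$gene_id)])
    }, 1))
  }
  r <- c(recovery_at(0), recovery_at(0.15), recovery_at(0.6))
  expect_equal(r[1], 1)
  expect_true(r[2] >= r[3] - 0.02)
  expect_true(r[1] >= r[2])
})

test_that("generated files pass the package validators round-trip", {
  ann <- simulate_annotation(30, c(chrA = 4e6), seed = 12)
  bk <- simulate_bulk(bulk_sim_params(), ann, seed = 12)
  dir <- withr::local_tempdir()
  write_expression_table(bk$table, file.path(dir, "expr.tsv"))
  expect_silent(read_expression_table(file.path(dir, "expr.tsv")))
  write_annotation(ann, file.path(dir, "ann.gtf"))
  expect_equal(read_annotation(file.path(dir, "ann.gtf"))$tss, ann$tss)
  sc <- simulate_sc(sc_sim_params(n_cells = 50, n_genes = 300), seed = 12)
  write_sc_counts(sc, file.path(dir, "sc"))
  back <- read_sc_counts(file.path(dir, "sc"))
  expect_equal(as.matrix(back$counts), as.matrix(sc$counts))
  expect_equal(back$pseudotime$pseudotime, sc$truth$pseudotime)
})
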