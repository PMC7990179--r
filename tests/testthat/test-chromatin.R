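make_peaks <- function(..., mark = "H3K27ac", sample = "pos_E11.5_1") {
  coords <- list(...)
  tibble::tibble(
    chrom = vapply(coords, `[[`, "", 1),
    start = as.integer(vapply(coords, function(x) as.integer(x[[2]]), 1L)),
    end = as.integer(vapply(coords, function(x) as.integer(x[[3]]), 1L)),
    score = NA_real_, mark = mark, sample = sample)
}

one_gene <- function(tss = 100000L, strand = "+") {
  start <- if (strand == "+") tss else tss - 9999L
  tibble::tibble(gene_id = "g", chrom = "chrT", strand = strand,
                 start = start, end = start + 10000L, biotype = "coding",
                 exons = list(tibble::tibble(start = start, end = start + 10000L))) |>
    validate_annotation()
}

test_that("TSS and distal windows classify peaks by position", {
  ann <- one_gene(100000L)
  near <- make_peaks(list("chrT", 96000, 97000))
  far <- make_peaks(list("chrT", 150000, 151000))
  out <- make_peaks(list("chrT", 250000, 251000))
  expect_true(assign_tss_binding(near, ann)$tss_bound)
  b_far <- assign_tss_binding(far, ann)
  expect_false(b_far$tss_bound); expect_true(b_far$distal_bound)
  b_out <- assign_tss_binding(out, ann)
  expect_false(b_out$tss_bound); expect_false(b_out$distal_bound)
  expect_error(assign_tss_binding(near, ann, tss_window = -1), "Windows")
})

test_that("binding flags equal the quadratic all-pairs oracle on random data", {
  set.seed(5)
  ann <- simulate_annotation(200, c(chrA = 2e7, chrB = 1e7), seed = 55)
  n_pk <- 500
  chrom <- sample(c("chrA", "chrB"), n_pk, replace = TRUE)
  s0 <- sample.int(2e7 - 2000, n_pk)
  peaks <- tibble::tibble(chrom = chrom, start = s0,
                          end = s0 + sample(200:2000, n_pk, replace = TRUE),
                          score = NA_real_,
                          mark = sample(c("H3K27ac", "H3K27me3"), n_pk, TRUE),
                          sample = "pos_E13.5_1")
  got <- assign_tss_binding(peaks, ann) |>
    dplyr::arrange(gene_id, mark, sample)
  want <- brute_force_binding(peaks, ann, 5000, 100000) |>
    dplyr::arrange(gene_id, mark, sample)
  expect_equal(got$tss_bound, want$tss_bound)
  expect_equal(got$distal_bound, want$distal_bound)
})

test_that("TSS state classification implements the four-way bivalency map", {
  expect_equal(classify_tss_state(c(TRUE, TRUE, FALSE, FALSE),
                                  c(TRUE, FALSE, TRUE, FALSE)),
               c("poised", "active", "repressed", "none"))
})

test_that("peak feature annotation follows promoter > exon > intron > intergenic", {
  ann <- tibble::tibble(
    gene_id = "g", chrom = "chrT", strand = "+", start = 100000L, end = 130000L,
    biotype = "coding",
    exons = list(tibble::tibble(start = c(100000L, 120000L),
                                end = c(101000L, 130000L)))) |>
    validate_annotation()
  pk <- make_peaks(
    list("chrT", 99500, 100500),   # overlaps promoter window and exon 1
    list("chrT", 125000, 126000),  # inside exon 2
    list("chrT", 110000, 111000),  # gene body between exons
    list("chrT", 500000, 501000))  # gene-free
  got <- annotate_peak_feature(pk, ann)
  expect_equal(got$feature, c("promoter", "exon", "intron", "intergenic"))
})

test_that("consistency across stages requires binding in all three positive samples", {
  mk_bind <- function(stages_bound) {
    tidyr::expand_grid(gene_id = "g", mark = "H3K27ac",
                       sample = paste0("pos_", stage_levels(), "_1")) |>
      dplyr::mutate(tss_bound = sub("pos_(E1[135].5)_1", "\\1", sample) %in% stages_bound,
                    distal_bound = FALSE)
  }
  expect_true(consistent_mark(mk_bind(stage_levels()), "H3K27ac")$consistent)
  expect_false(consistent_mark(mk_bind(c("E11.5", "E13.5")), "H3K27ac")$consistent)
  two_stages <- mk_bind(stage_levels()) |> dplyr::filter(sample != "pos_E15.5_1")
  expect_error(consistent_mark(two_stages, "H3K27ac"), "E15.5")
})

test_that("the chi-squared statistic matches its closed form and the stats oracle", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(c(20, 5, 5, 20))$statistic, 18)
  # transposition symmetry
  m <- matrix(c(13, 7, 4, 21), 2, 2)
  expect_equal(chi_square_2x2(m)$statistic, chi_square_2x2(t(m))$statistic)
  # independent oracle: stats::chisq.test without correction, 200 random tables
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 30) + 1, 2, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)),
              1e-10 * max(1, ours$statistic))
    expect_lt(abs(ours$p_value - ref$p.value), 1e-10)
  }
  # Yates agrees with the corrected oracle too
  yt <- chi_square_2x2(m, correct = TRUE)
  ref <- chisq.test(m, correct = TRUE)
  expect_equal(yt$statistic, unname(ref$statistic))
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("the histone-by-trend crosstab is conservative and detects construction", {
  universe <- sprintf("g%03d", 1:100)
  bindings <- tidyr::expand_grid(
    gene_id = universe, mark = "H3K27ac",
    sample = paste0("pos_", stage_levels(), "_1")) |>
    dplyr::mutate(tss_bound = gene_id %in% universe[1:50], distal_bound = FALSE)
  trends <- tibble::tibble(gene_id = universe,
                           trend = ifelse(gene_id %in% universe[1:50],
                                          "increasing", "other"))
  ct <- crosstab_histone_expression(bindings, trends, universe, "H3K27ac")
  expect_equal(sum(ct$table), 100)
  expect_equal(unname(ct$table[1, 1]), 50)
  expect_equal(unname(ct$table[2, 2]), 50)
  expect_lt(ct$test$p_value, 1e-15)
  expect_setequal(ct$cells$bound_trend, universe[1:50])
  expect_equal(sort(unlist(ct$cells, use.names = FALSE)), sort(universe))
  expect_error(crosstab_histone_expression(bindings, trends, character(0), "H3K27ac"),
               "Empty universe")
})

test_that("the chi-squared null rejection rate is calibrated near alpha", {
  set.seed(99)
  n_rej <- 0L; n_tot <- 2000L
  for (i in seq_len(n_tot)) {
    x <- rbinom(1, 200, 0.5); y <- rbinom(1, 200, 0.5)
    # two independent margins -> independent cell structure
    tab <- matrix(c(rhyper(1, x, 200 - x, y), 0, 0, 0), 2, 2)
    tab[1, 2] <- x - tab[1, 1]; tab[2, 1] <- y - tab[1, 1]
    tab[2, 2] <- 200 - x - tab[2, 1]
    p <- chi_square_2x2(tab)$p_value
    if (p < 0.05) n_rej <- n_rej + 1L
  }
  expect_gte(n_rej / n_tot, 0.03)
  expect_lte(n_rej / n_tot, 0.07)
})

test_that("the TSS/distal partition is a partition of the universe", {
  ann <- simulate_annotation(100, c(chrA = 1e7), seed = 61)
  bk <- simulate_bulk(bulk_sim_params(), ann, seed = 61)
  pk <- simulate_peaks(ann, bk$truth, chrom_sizes = c(chrA = 1e7), seed = 61)
  bindings <- assign_tss_binding(pk$peaks, ann)
  part <- partition_tss_distal(bindings, ann$gene_id, "H3K27ac")
  expect_equal(sum(part$n), 100)
  expect_equal(part$category, c("tss_only", "both", "distal_only", "neither"))
  expect_equal(part$pct, 100 * part$n / 100)
  # any-TSS minus tss_only equals both
  any_tss <- part$n[part$category %in% c("tss_only", "both")]
  expect_equal(sum(any_tss) - part$n[part$category == "tss_only"],
               part$n[part$category == "both"])
})

test_that("reversing a gene's strand moves its TSS and its bindings", {
  peak <- make_peaks(list("chrT", 96000, 97000))  # near the + TSS at 100000
  plus <- one_gene(100000L, "+")
  minus <- plus
  minus$strand <- "-"
  minus <- validate_annotation(minus)
  expect_equal(minus$tss, plus$end - 1L)
  b_plus <- assign_tss_binding(peak, plus)
  b_minus <- assign_tss_binding(peak, minus)
  expect_true(b_plus$tss_bound)
  expect_false(b_minus$tss_bound)   # TSS moved ~10 kb away
  expect_true(b_minus$distal_bound)
})
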