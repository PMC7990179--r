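#' Tidy a 2x2 chi-squared result
#'
#' @param x A `cr_chisq` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p_value`, `df`,
#'   `method`.
#' @export
tidy.cr_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, df = 1L,
         method = if (x$correct) "Pearson chi-squared (Yates)" else "Pearson chi-squared")
}

#' @rdname tidy.cr_chisq
#' @export
glance.cr_chisq <- function(x, ...) tidy(x, ...)

#' Tidy a histone-by-trend contingency analysis
#'
#' @param x A `cr_crosstab` object.
#' @param ... Unused.
#' @return `tidy()`: one row per cell with `binding`, `trend`, `n`;
#'   `glance()`: one row with the test results and universe size.
#' @export
tidy.cr_crosstab <- function(x, ...) {
  tibble(
    binding = rep(rownames(x$table), each = 2),
    trend = rep(colnames(x$table), 2),
    n = as.integer(t(x$table))
  )
}

#' @rdname tidy.cr_crosstab
#' @export
glance.cr_crosstab <- function(x, ...) {
  tibble(
    mark = x$mark, region = x$region, trend = x$trend,
    universe = x$universe_size,
    statistic = if (is.null(x$test)) NA_real_ else x$test$statistic,
    p_value = if (is.null(x$test)) NA_real_ else x$test$p_value
  )
}

#' Tidy a k-means clustering
#'
#' @param x A `cr_kmeans` object.
#' @param ... Unused.
#' @return `tidy()`: one row per cluster with its size and centre
#'   coordinates; `glance()`: one row with `k`, `tot_withinss`,
#'   `iterations`.
#' @export
tidy.cr_kmeans <- function(x, ...) {
  sizes <- x$assignment |> count(.data$cluster, name = "size")
  centers <- as_tibble(x$centers, .name_repair = ~ paste0("dim", seq_along(.x)))
  centers$cluster <- as.character(seq_len(nrow(centers)) - 1L)
  left_join(sizes, centers, by = "cluster")
}

#' @rdname tidy.cr_kmeans
#' @export
glance.cr_kmeans <- function(x, ...) {
  tibble(k = x$k, tot_withinss = x$tot_withinss, iterations = x$iterations,
         n_cells = nrow(x$assignment))
}

#' Tidy an integration report
#'
#' @param x An `integration_report`.
#' @param ... Unused.
#' @return `tidy()`: the temporal class-count table; `glance()`: one row
#'   of headline numbers (set sizes, bivalent fractions, chi-squared
#'   p-value, recovery statistics).
#' @export
tidy.integration_report <- function(x, ...) x$class_counts

#' @rdname tidy.integration_report
#' @export
glance.integration_report <- function(x, ...) {
  states_pos <- x$tables$tss_states |>
    filter(startsWith(.data$condition, "pos_"))
  states_neg <- x$tables$tss_states |>
    filter(startsWith(.data$condition, "neg_"))
  enr <- setNames(x$enrichment_summary$n, x$enrichment_summary$set)
  rec <- setNames(x$recovery$value, x$recovery$metric)
  tibble(
    n_genes = nrow(x$tables$expression),
    n_deg = sum(x$class_counts$n),
    n_classes_observed = sum(x$class_counts$n > 0),
    n_cr_specific = unname(enr["cr_specific"]),
    n_layer1 = unname(enr["layer1_candidate"]),
    n_cr_lncrna = unname(enr["cr_specific_lncRNA"]),
    pct_bivalent_pos = 100 * mean(states_pos$state == "poised"),
    pct_bivalent_neg = 100 * mean(states_neg$state == "poised"),
    chisq_ac_increasing_p = x$crosstabs$ac_tss_increasing$test$p_value,
    kmeans_ari = unname(rec["kmeans_ari"]),
    temporal_class_recovery = unname(rec["temporal_class_recovery"])
  )
}
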