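#' Per-stage replicate-mean FPKM by population
#'
#' @param table An expression table (see [read_expression_table()]).
#' @return A tibble `gene_id`, `stage`, `population`, `mean_fpkm` with the
#'   replicate mean per condition.
#' @export
stage_means <- function(table) {
  keys <- sample_key_info(table)
  table |>
    select(dplyr::all_of(c("gene_id", keys$column))) |>
    tidyr::pivot_longer(-"gene_id", names_to = "column", values_to = "fpkm") |>
    left_join(keys, by = "column") |>
    group_by(.data$gene_id, .data$stage, .data$population) |>
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop")
}

#' Pseudocounted positive/negative expression ratio per stage
#'
#' The enrichment statistic of the whole pipeline: the ratio of
#' replicate-mean FPKM in the reporter-positive population over the
#' reporter-negative population, with a pseudocount added to numerator and
#' denominator so that genes silent in both populations land at a ratio of
#' 1 ("unchanged") rather than 0/0.
#'
#' @param table An expression table.
#' @param stage A stage name, or `NULL` (default) for all three stages.
#' @param pseudocount Added to both means (default 0.1).
#' @return A tibble `gene_id`, `stage`, `mean_pos`, `mean_neg`, `ratio`.
#' @export
compute_stage_ratio <- function(table, stage = NULL, pseudocount = 0.1) {
  means <- stage_means(table)
  if (!is.null(stage)) {
    assert_stage(stage)
    if (!all(stage %in% means$stage)) {
      abort(paste0("Stage ", setdiff(stage, means$stage)[1], " absent from the table."))
    }
    means <- means |> filter(.data$stage %in% !!stage)
  }
  wide <- means |>
    tidyr::pivot_wider(names_from = "population", values_from = "mean_fpkm",
                       names_prefix = "mean_")
  if (!all(c("mean_pos", "mean_neg") %in% names(wide))) {
    abort("Both populations are required to form a ratio.")
  }
  wide |>
    mutate(ratio = (.data$mean_pos + pseudocount) / (.data$mean_neg + pseudocount)) |>
    arrange(.data$gene_id, factor(.data$stage, stage_levels()))
}

#' Stage-wise enriched genes
#'
#' A gene is enriched in the reporter-positive population at a stage when
#' its mean positive FPKM exceeds 1 (strictly) and the pos/neg ratio is at
#' least 2.
#'
#' @param ratios Ratio tibble from [compute_stage_ratio()].
#' @param stage Stage to call.
#' @param min_fpkm,fc_threshold Expression floor (strict) and fold-change
#'   threshold (inclusive).
#' @return Character vector of enriched gene ids (sorted).
#' @export
call_enriched <- function(ratios, stage, min_fpkm = 1, fc_threshold = 2) {
  assert_stage(stage)
  r <- ratios |> filter(.data$stage == !!stage)
  if (nrow(r) == 0L) abort(paste0("No ratios for stage ", stage, "."))
  sort(r$gene_id[r$mean_pos > min_fpkm & r$ratio >= fc_threshold])
}

#' Consistently enriched (CR-specific) genes
#'
#' Genes with mean positive-population FPKM of at least 5 and a fold change
#' of at least 2 at every one of the three stages.
#'
#' @inheritParams call_enriched
#' @param min_fpkm Inclusive positive-population FPKM floor (default 5).
#' @return Sorted character vector of gene ids.
#' @export
call_cr_specific <- function(ratios, min_fpkm = 5, fc_threshold = 2) {
  if (!setequal(unique(ratios$stage), stage_levels())) {
    abort("call_cr_specific() needs ratios at all three stages.")
  }
  ratios |>
    group_by(.data$gene_id) |>
    summarise(ok = all(.data$mean_pos >= min_fpkm & .data$ratio >= fc_threshold),
              .groups = "drop") |>
    filter(.data$ok) |>
    pull("gene_id") |>
    sort()
}

#' Remove genes on curated exclusion lists
#'
#' Set difference of a candidate set against the union of exclusion lists
#' (e.g. previously reported subplate and Cajal-Retzius marker genes),
#' leaving novel candidates.
#'
#' @param candidates Character vector of gene ids.
#' @param exclusions A list of character vectors (may be empty).
#' @return Sorted character vector.
#' @export
apply_exclusion_lists <- function(candidates, exclusions = list()) {
  sort(setdiff(candidates, unique(unlist(exclusions))))
}

#' Layer-1 candidate filter
#'
#' Restricts a CR-specific gene set to genes whose reporter-negative mean
#' FPKM stays at or below a ceiling (default 15) at all three stages, i.e.
#' genes expressed in layer-1 cells but essentially silent in the rest of
#' the cortex.
#'
#' @param cr_specific Character vector of gene ids.
#' @param ratios Ratio tibble from [compute_stage_ratio()] covering them.
#' @param neg_max_fpkm Inclusive negative-population ceiling.
#' @return Sorted character vector.
#' @export
call_layer1_candidates <- function(cr_specific, ratios, neg_max_fpkm = 15) {
  if (length(cr_specific) == 0L) return(character(0))
  missing <- setdiff(cr_specific, ratios$gene_id)
  if (length(missing) > 0L) {
    abort(paste0("Gene(s) absent from the ratio table: ",
                 paste(missing, collapse = ", ")))
  }
  ratios |>
    filter(.data$gene_id %in% cr_specific) |>
    group_by(.data$gene_id) |>
    summarise(ok = all(.data$mean_neg <= neg_max_fpkm), .groups = "drop") |>
    filter(.data$ok) |>
    pull("gene_id") |>
    sort()
}

#' Differentially expressed lncRNAs
#'
#' lncRNA-biotype genes passing the differential-expression gates carried
#' in the table (`de_fdr < 0.05` and `de_p < 0.01` by default; the
#' statistics themselves are inputs, computed upstream).
#'
#' @param table Expression table with `biotype`, `de_p`, `de_fdr`.
#' @param max_fdr,max_p Gate thresholds (strict).
#' @return Sorted character vector of lncRNA gene ids.
#' @export
call_de_lncrna <- function(table, max_fdr = 0.05, max_p = 0.01) {
  if (!all(c("biotype", "de_p", "de_fdr") %in% names(table))) {
    abort("call_de_lncrna() needs biotype, de_p and de_fdr columns.")
  }
  lnc <- table |> filter(.data$biotype == "lncRNA")
  bad <- lnc$gene_id[is.na(lnc$de_p) | is.na(lnc$de_fdr)]
  if (length(bad) > 0L) {
    abort(paste0("Missing DE statistics for lncRNA(s): ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  sort(lnc$gene_id[lnc$de_fdr < max_fdr & lnc$de_p < max_p])
}

#' CR-specific lncRNA cascade
#'
#' Restricts differentially expressed lncRNAs to those with a fold change
#' of at least 2 at every stage, a reporter-negative mean FPKM of at most
#' 15 at every stage, and a reporter-positive mean FPKM of at least 5 at
#' the last stage (E15.5).
#'
#' @param de_lncrnas Character vector from [call_de_lncrna()].
#' @param ratios Ratio tibble covering all three stages.
#' @param fc_threshold,neg_max_fpkm,pos_min_fpkm_last Gate values.
#' @return Sorted character vector.
#' @export
call_cr_specific_lncrna <- function(de_lncrnas, ratios, fc_threshold = 2,
                                    neg_max_fpkm = 15, pos_min_fpkm_last = 5) {
  if (length(de_lncrnas) == 0L) return(character(0))
  last_stage <- stage_levels()[3]
  ratios |>
    filter(.data$gene_id %in% de_lncrnas) |>
    group_by(.data$gene_id) |>
    summarise(
      ok = all(.data$ratio >= fc_threshold) &
        all(.data$mean_neg <= neg_max_fpkm) &
        any(.data$stage == last_stage & .data$mean_pos >= pos_min_fpkm_last),
      .groups = "drop") |>
    filter(.data$ok) |>
    pull("gene_id") |>
    sort()
}

#' Pearson correlation between replicates of one condition
#'
#' Computed between log(FPKM + 1) replicate vectors, the scale on which
#' replicate concordance of expression data is normally judged.
#'
#' @param table Expression table.
#' @param population,stage The condition.
#' @param rep_pair Which two replicates to compare (default 1 and 2).
#' @return Pearson r (length-1 numeric).
#' @export
replicate_correlation <- function(table, population, stage, rep_pair = c(1L, 2L)) {
  assert_stage(stage)
  cols <- make_sample_key(population, stage, rep_pair)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0L) {
    abort(paste0("Replicate column(s) absent: ", paste(missing, collapse = ", ")))
  }
  x <- log1p(table[[cols[1]]])
  y <- log1p(table[[cols[2]]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("A replicate vector is constant; Pearson r is undefined.")
  }
  cor(x, y)
}

#' One-row-per-gene summary of all enrichment calls
#'
#' Convenience wrapper running the whole coding-gene cascade: per-stage
#' enrichment, CR-specific, novel (after exclusion lists) and layer-1
#' flags.
#'
#' @param table Expression table.
#' @param exclusions List of exclusion gene-id vectors.
#' @param pseudocount,fc_threshold,pos_min_fpkm,neg_max_fpkm Cascade
#'   parameters (see the individual callers).
#' @return A tibble with one row per gene and logical flag columns
#'   `enriched_E11.5`, `enriched_E13.5`, `enriched_E15.5`, `cr_specific`,
#'   `novel_candidate`, `layer1_candidate`.
#' @export
enrichment_calls <- function(table, exclusions = list(), pseudocount = 0.1,
                             fc_threshold = 2, pos_min_fpkm = 5,
                             neg_max_fpkm = 15) {
  ratios <- compute_stage_ratio(table, pseudocount = pseudocount)
  cr <- call_cr_specific(ratios, min_fpkm = pos_min_fpkm,
                         fc_threshold = fc_threshold)
  novel <- apply_exclusion_lists(cr, exclusions)
  layer1 <- call_layer1_candidates(cr, ratios, neg_max_fpkm = neg_max_fpkm)
  out <- tibble(gene_id = sort(unique(table$gene_id)))
  for (s in stage_levels()) {
    out[[paste0("enriched_", s)]] <-
      out$gene_id %in% call_enriched(ratios, s, fc_threshold = fc_threshold)
  }
  out$cr_specific <- out$gene_id %in% cr
  out$novel_candidate <- out$gene_id %in% novel
  out$layer1_candidate <- out$gene_id %in% layer1
  out
}

#' Benjamini-Hochberg FDR for user-supplied p-values
#'
#' Helper for tables that arrive with `de_p` but no `de_fdr`.
#'
#' @param table Expression table with `de_p`.
#' @return The table with a `de_fdr` column appended.
#' @export
add_bh_fdr <- function(table) {
  if (!"de_p" %in% names(table)) abort("No de_p column to adjust.")
  table$de_fdr <- p.adjust(table$de_p, method = "BH")
  table
}
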