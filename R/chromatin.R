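#' Assign peaks to TSS and distal windows per gene
#'
#' A gene is `tss_bound` for a mark/sample when any peak overlaps the
#' half-open window `[TSS - w, TSS + w)` (default w = 5 kb), and
#' `distal_bound` when any peak overlaps the wider window `[TSS - W,
#' TSS + W)` (default W = 100 kb) without itself overlapping the TSS
#' window — i.e. the distal call is anchored at the TSS and excludes
#' promoter-overlapping peaks. Overlap is any-base overlap of half-open
#' intervals, strand only enters through the TSS position.
#'
#' @param peaks Peak tibble (as from [read_peaks()]; may hold several
#'   marks/samples).
#' @param annotation Annotation tibble.
#' @param tss_window,distal_window Window half-widths in bp.
#' @return A tibble `gene_id`, `mark`, `sample`, `tss_bound`,
#'   `distal_bound` covering every gene x mark x sample combination
#'   present in `peaks`.
#' @export
assign_tss_binding <- function(peaks, annotation, tss_window = 5000L,
                               distal_window = 100000L) {
  if (tss_window <= 0 || distal_window <= tss_window) {
    abort("Windows must satisfy 0 < tss_window < distal_window.")
  }
  groups <- peaks |> distinct(.data$mark, .data$sample)
  tss_gr <- annotation_tss_granges(annotation, tss_window)
  dist_gr <- annotation_tss_granges(annotation, distal_window)
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    p <- peaks |>
      filter(.data$mark == groups$mark[i], .data$sample == groups$sample[i])
    pg <- peaks_granges(p)
    tss_hits <- GenomicRanges::findOverlaps(tss_gr, pg)
    dist_hits <- GenomicRanges::findOverlaps(dist_gr, pg)
    # peaks overlapping ANY gene's TSS window, per (gene, peak) pair:
    # a distal pair stands only if that same peak misses this gene's window
    tss_pairs <- paste(S4Vectors::queryHits(tss_hits), S4Vectors::subjectHits(tss_hits))
    dist_pairs <- paste(S4Vectors::queryHits(dist_hits), S4Vectors::subjectHits(dist_hits))
    distal_genes <- unique(S4Vectors::queryHits(dist_hits)[!(dist_pairs %in% tss_pairs)])
    out[[i]] <- tibble(
      gene_id = annotation$gene_id,
      mark = groups$mark[i],
      sample = groups$sample[i],
      tss_bound = seq_len(nrow(annotation)) %in% S4Vectors::queryHits(tss_hits),
      distal_bound = seq_len(nrow(annotation)) %in% distal_genes
    )
  }
  bind_rows(out)
}

#' Four-state TSS chromatin classification
#'
#' Monovalent H3K27ac marks an active promoter, monovalent H3K27me3 a
#' repressed one, both together a poised (bivalent) promoter, neither is
#' `none`.
#'
#' @param ac_bound,me3_bound Logical vectors (recycled together).
#' @return Character vector over
#'   `{"active", "repressed", "poised", "none"}`.
#' @export
#' @examples
#' classify_tss_state(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
classify_tss_state <- function(ac_bound, me3_bound) {
  dplyr::case_when(ac_bound & me3_bound ~ "poised",
                   ac_bound ~ "active",
                   me3_bound ~ "repressed",
                   .default = "none")
}

#' Per-gene, per-condition TSS chromatin states from binding flags
#'
#' Folds a binding table over its two marks; replicate sample keys of the
#' same population/stage are first collapsed by any-replicate union. A
#' mark with no rows for a condition counts as unbound.
#'
#' @param bindings Tibble from [assign_tss_binding()].
#' @return A tibble `gene_id`, `condition` (`<pop>_<stage>`), `ac`, `me3`,
#'   `state`.
#' @export
tss_states <- function(bindings) {
  keys <- parse_sample_key(paste0(bindings$sample, ifelse(
    grepl("_[0-9]+$", bindings$sample), "", "_1")))
  cond <- paste(keys$population, keys$stage, sep = "_")
  bindings |>
    mutate(condition = cond) |>
    group_by(.data$gene_id, .data$condition, .data$mark) |>
    summarise(bound = any(.data$tss_bound), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "mark", values_from = "bound",
                       values_fill = FALSE) |>
    (\(d) {
      d$ac <- if ("H3K27ac" %in% names(d)) d$H3K27ac else FALSE
      d$me3 <- if ("H3K27me3" %in% names(d)) d$H3K27me3 else FALSE
      d
    })() |>
    mutate(state = classify_tss_state(.data$ac, .data$me3)) |>
    select("gene_id", "condition", "ac", "me3", "state") |>
    arrange(.data$gene_id, .data$condition)
}

#' Annotate peaks with the genomic feature they fall in
#'
#' Priority promoter > exon > intron > intergenic: a peak overlapping a
#' promoter window (TSS +/- `promoter_window`, default 2 kb) is `promoter`
#' regardless of exon overlap; otherwise exon overlap wins over intron
#' (inside a gene span with no exon overlap); peaks outside every gene
#' span are `intergenic`.
#'
#' @param peaks Peak tibble.
#' @param annotation Annotation tibble.
#' @param promoter_window Promoter half-width in bp.
#' @return The peak tibble with a `feature` column appended.
#' @export
annotate_peak_feature <- function(peaks, annotation, promoter_window = 2000L) {
  pg <- peaks_granges(peaks)
  prom <- annotation_tss_granges(annotation, promoter_window)
  exon_tbl <- annotation |>
    select("gene_id", "chrom", "exons") |>
    tidyr::unnest("exons")
  exon_gr <- GenomicRanges::GRanges(
    exon_tbl$chrom, IRanges::IRanges(exon_tbl$start + 1L, exon_tbl$end))
  span_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start + 1L, annotation$end))
  in_prom <- GenomicRanges::countOverlaps(pg, prom) > 0L
  in_exon <- GenomicRanges::countOverlaps(pg, exon_gr) > 0L
  in_span <- GenomicRanges::countOverlaps(pg, span_gr) > 0L
  peaks |>
    mutate(feature = dplyr::case_when(
      in_prom ~ "promoter",
      in_exon ~ "exon",
      in_span ~ "intron",
      .default = "intergenic"
    ))
}

#' Consistent TSS binding of one mark across the three positive stages
#'
#' @param bindings Tibble from [assign_tss_binding()].
#' @param mark Mark to test.
#' @param population Population whose stages are required (default
#'   `"pos"`).
#' @param region `"tss"` or `"distal"` binding flags.
#' @return A tibble `gene_id`, `consistent` (TRUE iff bound at all three
#'   stages). Errors when a stage has no samples for the mark.
#' @export
consistent_mark <- function(bindings, mark, population = "pos",
                            region = c("tss", "distal")) {
  region <- match.arg(region)
  keys <- parse_sample_key(bindings$sample)
  b <- bindings |>
    mutate(population = keys$population, stage = keys$stage) |>
    filter(.data$mark == !!mark, .data$population == !!population)
  present <- unique(b$stage)
  if (!all(stage_levels() %in% present)) {
    abort(paste0("No ", mark, " samples for stage(s): ",
                 paste(setdiff(stage_levels(), present), collapse = ", ")))
  }
  flag <- if (region == "tss") "tss_bound" else "distal_bound"
  b |>
    group_by(.data$gene_id, .data$stage) |>
    summarise(bound = any(.data[[flag]]), .groups = "drop") |>
    group_by(.data$gene_id) |>
    summarise(consistent = sum(.data$bound) == 3L, .groups = "drop")
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' The closed-form statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' with an optional Yates continuity correction, and the upper-tail
#' p-value from the chi-squared distribution with one degree of freedom.
#'
#' @param tab A 2x2 numeric matrix (counts), or a length-4 vector
#'   `c(a, b, c, d)` read row-wise.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return An object of class `cr_chisq`: list with `statistic`,
#'   `p_value`, `table`, `correct`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (!all(dim(tab) == c(2L, 2L))) abort("chi_square_2x2() needs a 2x2 table.")
  if (any(tab < 0) || any(!is.finite(tab))) abort("Counts must be finite and >= 0.")
  n <- sum(tab)
  if (n <= 0) abort("Empty table.")
  margins <- c(rowSums(tab), colSums(tab))
  if (any(margins == 0)) abort("A zero margin makes the test undefined.")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  num <- abs(a * d - b * c_)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  structure(
    list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         table = tab, correct = correct),
    class = "cr_chisq")
}

#' @export
print.cr_chisq <- function(x, ...) {
  cat("2x2 Pearson chi-squared test",
      if (x$correct) "(Yates-corrected)" else "(no continuity correction)", "\n")
  print(x$table)
  cat(sprintf("X-squared = %.4f, df = 1, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Histone-mark x expression-trend contingency analysis
#'
#' Cross-tabulates consistent TSS (or distal) binding of a mark across the
#' three positive stages against an expression-trend category over a gene
#' universe, runs the chi-squared test, and returns the gene lists behind
#' each cell.
#'
#' @param bindings Tibble from [assign_tss_binding()].
#' @param trends Tibble from [trend_category()].
#' @param universe Character vector of gene ids (non-empty).
#' @param mark Mark to test.
#' @param region `"tss"` or `"distal"`.
#' @param trend Trend level forming the positive column (default
#'   `"increasing"`; use `"low_decreasing"` for the low-expression
#'   variant).
#' @param correct Yates correction flag passed to [chi_square_2x2()].
#' @return An object of class `cr_crosstab`: list with `table` (2x2
#'   matrix, rows bound/unbound, columns trend/other), `test`
#'   (`cr_chisq`), `cells` (named list of gene-id vectors), `mark`,
#'   `region`, `trend`, `universe_size`.
#' @export
crosstab_histone_expression <- function(bindings, trends, universe, mark,
                                        region = c("tss", "distal"),
                                        trend = "increasing", correct = FALSE) {
  region <- match.arg(region)
  if (length(universe) == 0L) abort("Empty universe.")
  cons <- consistent_mark(bindings, mark, region = region)
  df <- tibble(gene_id = universe) |>
    left_join(cons, by = "gene_id") |>
    left_join(trends, by = "gene_id") |>
    mutate(consistent = dplyr::coalesce(.data$consistent, FALSE),
           hit = !is.na(.data$trend) & .data$trend == !!trend)
  tab <- matrix(c(sum(df$consistent & df$hit), sum(df$consistent & !df$hit),
                  sum(!df$consistent & df$hit), sum(!df$consistent & !df$hit)),
                2, 2, byrow = TRUE,
                dimnames = list(c("bound", "unbound"), c(trend, "other")))
  cells <- list(
    bound_trend = df$gene_id[df$consistent & df$hit],
    bound_other = df$gene_id[df$consistent & !df$hit],
    unbound_trend = df$gene_id[!df$consistent & df$hit],
    unbound_other = df$gene_id[!df$consistent & !df$hit])
  test <- tryCatch(chi_square_2x2(tab, correct = correct), error = function(e) NULL)
  structure(
    list(table = tab, test = test, cells = cells, mark = mark, region = region,
         trend = trend, universe_size = length(universe)),
    class = "cr_crosstab")
}

#' @export
print.cr_crosstab <- function(x, ...) {
  cat(sprintf("%s %s binding x '%s' trend over %d genes\n",
              x$mark, x$region, x$trend, x$universe_size))
  print(x$table)
  if (!is.null(x$test)) {
    cat(sprintf("X-squared = %.4f, p = %.4g\n", x$test$statistic, x$test$p_value))
  }
  invisible(x)
}

#' TSS/distal binding partition of a gene universe
#'
#' Splits a universe into the four disjoint categories `tss_only`, `both`,
#' `distal_only`, `neither` for one mark (any positive-population sample),
#' with percentages of the universe.
#'
#' @param bindings Tibble from [assign_tss_binding()].
#' @param universe Character vector of gene ids.
#' @param mark Mark to partition on.
#' @param population Population whose samples are folded (default "pos").
#' @return A tibble `category`, `n`, `pct`, four rows summing to
#'   `length(universe)`.
#' @export
partition_tss_distal <- function(bindings, universe, mark, population = "pos") {
  keys <- parse_sample_key(bindings$sample)
  b <- bindings |>
    mutate(population = keys$population) |>
    filter(.data$mark == !!mark, .data$population == !!population) |>
    group_by(.data$gene_id) |>
    summarise(tss = any(.data$tss_bound), distal = any(.data$distal_bound),
              .groups = "drop")
  df <- tibble(gene_id = universe) |>
    left_join(b, by = "gene_id") |>
    mutate(tss = dplyr::coalesce(.data$tss, FALSE),
           distal = dplyr::coalesce(.data$distal, FALSE))
  cats <- c("tss_only", "both", "distal_only", "neither")
  cat_of <- dplyr::case_when(df$tss & df$distal ~ "both",
                             df$tss ~ "tss_only",
                             df$distal ~ "distal_only",
                             .default = "neither")
  counts <- table(factor(cat_of, levels = cats))
  tibble(category = cats, n = as.integer(counts),
         pct = 100 * as.integer(counts) / length(universe))
}
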