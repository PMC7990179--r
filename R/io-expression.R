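#' Read and write genes-by-samples FPKM tables
#'
#' An expression table is a tibble with one row per gene: `gene_id`, an
#' optional `biotype` column (`coding` / `lncRNA`), optional differential-
#' expression statistics `de_p` and `de_fdr` (consumed as inputs — the
#' upstream DE engine is out of scope), and one numeric FPKM column per
#' sample named `<pop>_<stage>_<rep>`.
#'
#' `read_expression_table()` validates the file hard: duplicated `gene_id`,
#' negative or non-numeric FPKM values, and `de_fdr < de_p` rows are errors
#' naming the offending gene/column. Columns that are neither `gene_id`,
#' recognised metadata nor parseable sample keys are reported with a warning
#' and kept untouched.
#'
#' @param path Path to a tab-separated file with a header row; first column
#'   `gene_id`.
#' @return A tibble (the expression table).
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "gene_id"
  validate_expression_table(tab)
}

#' @rdname read_expression_table
#' @param table An expression table.
#' @export
write_expression_table <- function(table, path) {
  table <- validate_expression_table(table)
  keys <- sample_key_info(table)
  keys <- keys |>
    mutate(
      population = factor(.data$population, population_levels()),
      stage = factor(.data$stage, stage_levels())
    ) |>
    arrange(.data$population, .data$stage, .data$replicate)
  meta <- intersect(c("biotype", "de_p", "de_fdr"), names(table))
  out <- table |>
    select(dplyr::all_of(c("gene_id", meta, keys$column))) |>
    arrange(.data$gene_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expression_table
#' @export
validate_expression_table <- function(table) {
  table <- as_tibble(table)
  if (!"gene_id" %in% names(table)) abort("Expression table needs a 'gene_id' column.")
  dup <- table$gene_id[duplicated(table$gene_id)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicated gene_id: ", paste(unique(dup), collapse = ", ")))
  }
  keys <- sample_key_info(table)
  for (col in keys$column) {
    v <- table[[col]]
    if (!is.numeric(v)) abort(paste0("FPKM column '", col, "' is not numeric."))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      abort(paste0(
        "Negative or non-finite FPKM in column '", col, "' for gene ",
        table$gene_id[bad[1]], " (row ", bad[1], ")."
      ))
    }
  }
  if ("de_fdr" %in% names(table)) {
    if (!"de_p" %in% names(table)) abort("de_fdr present without de_p.")
    both <- !is.na(table$de_fdr) & !is.na(table$de_p)
    bad <- which(both & table$de_fdr < table$de_p)
    if (length(bad) > 0L) {
      abort(paste0(
        "de_fdr < de_p for gene ", table$gene_id[bad[1]],
        "; FDR can never undercut its p-value."
      ))
    }
  }
  known <- c("gene_id", "biotype", "de_p", "de_fdr", keys$column)
  extra <- setdiff(names(table), known)
  if (length(extra) > 0L) {
    warn(paste0("Unmapped columns kept as-is: ", paste(extra, collapse = ", ")))
  }
  table
}

#' Read and write plain-text gene sets
#'
#' Gene sets (curated marker lists, exclusion lists, transcription-factor
#' target lists) are one gene id per line; blank lines and `#` comments are
#' ignored. Writers emit sorted, unique ids so output is deterministic.
#'
#' @param path File path.
#' @return `read_gene_set()` returns a character vector of unique gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' @rdname read_gene_set
#' @param genes Character vector of gene ids.
#' @export
write_gene_set <- function(genes, path) {
  readr::write_lines(sort(unique(genes)), path)
  invisible(path)
}
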