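#' Read ChIP-seq peak intervals (BED3+ / narrowPeak)
#'
#' Peaks are stored 0-based half-open, sorted by (chrom, start), with the
#' histone mark and the sample key attached to every record. BED columns
#' beyond the third are optional; when a narrowPeak-style score column
#' (column 5) is present it is preserved in `score`.
#'
#' @param path Path to a BED3+ or narrowPeak file (tab- or space-separated,
#'   no header; `track`/`browser`/`#` lines are skipped).
#' @param mark Histone mark label, e.g. `"H3K27ac"` or `"H3K27me3"`.
#' @param sample Sample key string, e.g. `"pos_E11.5_1"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `score`, `mark`,
#'   `sample`.
#' @export
read_peaks <- function(path, mark, sample) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  score = numeric(), mark = character(), sample = character()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  n_f <- lengths(fields)
  if (any(n_f < 3L)) {
    abort(paste0("Malformed peak line ", idx[which(n_f < 3L)[1]],
                 ": fewer than 3 fields."))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(paste0("Malformed peak line ", idx[bad[1]], ": non-numeric coordinates."))
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    abort(paste0("Peak line ", idx[bad[1]], " has start >= end (",
                 start[bad[1]], " >= ", end[bad[1]], ")."))
  }
  score <- rep(NA_real_, length(idx))
  has5 <- n_f >= 5L
  score[has5] <- suppressWarnings(as.numeric(
    vapply(fields[has5], `[[`, "", 5L)))
  tibble(chrom = chrom, start = start, end = end, score = score,
         mark = mark, sample = sample) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' @rdname read_peaks
#' @param peaks A peak tibble (at least `chrom`, `start`, `end`).
#' @export
write_peaks <- function(peaks, path) {
  peaks <- peaks |> arrange(.data$chrom, .data$start, .data$end)
  if (any(peaks$start >= peaks$end)) abort("Peak with start >= end.")
  name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  score <- if ("score" %in% names(peaks)) {
    if_else(is.na(peaks$score), 0, peaks$score)
  } else rep(0, nrow(peaks))
  readr::write_tsv(
    tibble(peaks$chrom, peaks$start, peaks$end, name, score),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Merge replicate peak sets for one mark and condition
#'
#' Replicate handling upstream of binding assignment: `union` (default)
#' keeps every interval covered by any replicate; `intersection` keeps only
#' regions covered by all replicates.
#'
#' @param peaks A peak tibble whose `sample` column holds >= 1 replicates of
#'   one population/stage.
#' @param method `"union"` or `"intersection"`.
#' @return A peak tibble with merged intervals; `sample` is collapsed to the
#'   common `<pop>_<stage>` prefix and `score` dropped.
#' @export
merge_replicate_peaks <- function(peaks, method = c("union", "intersection")) {
  method <- match.arg(method)
  stopifnot(nrow(peaks) > 0L)
  keys <- parse_sample_key(unique(peaks$sample))
  if (any(is.na(keys$population))) abort("Unparseable sample keys in peak set.")
  if (dplyr::n_distinct(keys$population, keys$stage) != 1L) {
    abort("merge_replicate_peaks() expects replicates of a single condition.")
  }
  gr <- peaks_granges(peaks)
  merged <- if (method == "union" || dplyr::n_distinct(peaks$sample) == 1L) {
    GenomicRanges::reduce(gr)
  } else {
    by_rep <- lapply(split(peaks, peaks$sample), peaks_granges)
    Reduce(GenomicRanges::intersect, lapply(by_rep, GenomicRanges::reduce))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    score = NA_real_,
    mark = peaks$mark[1],
    sample = paste(keys$population[1], keys$stage[1], sep = "_")
  ) |>
    arrange(.data$chrom, .data$start, .data$end)
}
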