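#' Emit ChIP-seq peak sets consistent with planted TSS chromatin states
#'
#' For every condition in the bulk truth (`state_*` columns) and each mark,
#' a gene whose planted state includes the mark (active or poised for
#' H3K27ac; repressed or poised for H3K27me3) receives one peak overlapping
#' its TSS window. Genes flagged with distal binding receive one peak
#' inside the distal window but wholly outside every gene's TSS window
#' (re-sampled up to 25 times; unplaceable distal peaks are dropped and the
#' returned truth updated accordingly). Optional background peaks are
#' scattered uniformly per chromosome at `background_rate` peaks/Mb; with
#' the rate at 0, re-deriving TSS states from the emitted peaks reproduces
#' the planted states exactly.
#'
#' @param annotation Annotation tibble.
#' @param truth Truth tibble from [simulate_bulk()].
#' @param chrom_sizes Named chromosome lengths (bp) for background/clipping.
#' @param tss_window,distal_window Half-widths in bp (defaults 5 kb/100 kb).
#' @param peak_width Emitted peak width in bp.
#' @param background_rate Background peaks per Mb per mark per condition.
#' @param replicate Replicate suffix attached to the emitted sample keys.
#' @param seed Integer seed.
#' @return A list: `peaks`, one tibble of all peak records (columns as
#'   [read_peaks()]), and `truth`, the input truth with unplaceable distal
#'   flags cleared.
#' @export
simulate_peaks <- function(annotation, truth,
                           chrom_sizes = NULL,
                           tss_window = 5000L, distal_window = 100000L,
                           peak_width = 600L, background_rate = 0,
                           replicate = 1L, seed = 1L) {
  if (tss_window <= 0 || distal_window <= tss_window) {
    abort("tss_window must be > 0 and distal_window > tss_window.")
  }
  if (!all(annotation$gene_id %in% truth$gene_id)) {
    abort("truth must cover every annotated gene.")
  }
  set.seed(seed)
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(annotation$end, annotation$chrom, max) + distal_window
  }
  conds <- sub("^state_", "", grep("^state_", names(truth), value = TRUE))
  marks <- c("H3K27ac", "H3K27me3")
  forbidden <- annotation_tss_granges(annotation, tss_window)
  out <- list()
  for (cond in conds) {
    sample_key <- paste0(cond, "_", replicate)
    state <- truth[[paste0("state_", cond)]]
    for (mk in marks) {
      has_tss <- state %in% if (mk == "H3K27ac") c("active", "poised") else c("repressed", "poised")
      jitter <- sample(seq(-tss_window + peak_width, tss_window - peak_width),
                       sum(has_tss), replace = TRUE)
      centre <- annotation$tss[has_tss] + jitter %/% 2L
      tss_peaks <- tibble(
        chrom = annotation$chrom[has_tss],
        start = pmax(0L, as.integer(centre - peak_width %/% 2L)),
        end = as.integer(centre + peak_width %/% 2L)
      )
      dist_col <- paste("distal", mk, cond, sep = "_")
      wants_distal <- if (dist_col %in% names(truth)) truth[[dist_col]] else rep(FALSE, nrow(truth))
      placed <- place_distal_peaks(annotation, which(wants_distal), forbidden,
                                   tss_window, distal_window, peak_width, chrom_sizes)
      if (dist_col %in% names(truth)) {
        truth[[dist_col]][setdiff(which(wants_distal), placed$gene_row)] <- FALSE
      }
      bg <- simulate_background_peaks(chrom_sizes, background_rate, peak_width)
      out[[paste(cond, mk, sep = ".")]] <- bind_rows(tss_peaks, placed$peaks, bg) |>
        mutate(score = NA_real_, mark = mk, sample = sample_key) |>
        arrange(.data$chrom, .data$start, .data$end)
    }
  }
  list(peaks = bind_rows(out), truth = truth)
}

place_distal_peaks <- function(annotation, rows, forbidden, tss_window,
                               distal_window, peak_width, chrom_sizes) {
  if (length(rows) == 0L) {
    return(list(peaks = tibble(chrom = character(), start = integer(), end = integer()),
                gene_row = integer()))
  }
  pending <- rows
  placed <- tibble(chrom = character(), start = integer(), end = integer(),
                   gene_row = integer())
  for (try in 1:25) {
    if (length(pending) == 0L) break
    tss <- annotation$tss[pending]
    chrom <- annotation$chrom[pending]
    size <- unname(unlist(chrom_sizes)[chrom])
    d <- sample(seq(tss_window + peak_width, distal_window - peak_width),
                length(pending), replace = TRUE)
    side <- sample(c(-1L, 1L), length(pending), replace = TRUE)
    centre <- tss + side * d
    s0 <- as.integer(centre - peak_width %/% 2L)
    e0 <- as.integer(centre + peak_width %/% 2L)
    in_bounds <- s0 >= 0L & e0 <= size
    hits_tss <- rep(TRUE, length(pending))
    if (any(in_bounds)) {
      cand <- GenomicRanges::GRanges(
        chrom[in_bounds], IRanges::IRanges(s0[in_bounds] + 1L, e0[in_bounds]))
      hits_tss[in_bounds] <-
        GenomicRanges::countOverlaps(cand, forbidden) > 0L
    }
    ok <- in_bounds & !hits_tss
    placed <- bind_rows(placed, tibble(chrom = chrom[ok], start = s0[ok],
                                       end = e0[ok], gene_row = pending[ok]))
    pending <- pending[!ok]
  }
  list(peaks = placed |> select("chrom", "start", "end"),
       gene_row = placed$gene_row)
}

simulate_background_peaks <- function(chrom_sizes, rate_per_mb, peak_width) {
  if (rate_per_mb <= 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- list()
  for (chrom in names(chrom_sizes)) {
    n_bg <- rpois(1, rate_per_mb * chrom_sizes[[chrom]] / 1e6)
    if (n_bg == 0L) next
    s0 <- sample.int(max(1L, as.integer(chrom_sizes[[chrom]] - peak_width)), n_bg,
                     replace = TRUE) - 1L
    out[[chrom]] <- tibble(chrom = chrom, start = s0,
                           end = s0 + as.integer(peak_width))
  }
  bind_rows(out)
}
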