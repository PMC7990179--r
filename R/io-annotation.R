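#' Read a gene annotation from GTF
#'
#' Gene models are stored as a tibble with 0-based half-open coordinates
#' (BED convention) throughout the package; GTF's 1-based closed intervals
#' are converted on read. The transcription start site is strand-aware:
#' `start` on the + strand, `end - 1` (the last covered base) on the -
#' strand. Exons live in a list-column of `start`/`end` tibbles, sorted and
#' checked to be non-overlapping and inside the gene span.
#'
#' @param path Path to a GTF file with `gene` and `exon` features. Gene
#'   biotype is taken from the `gene_biotype` (or `gene_type`) attribute
#'   when present, else `coding`.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `biotype`, `exons` (list-column).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) abort("GTF lacks a feature type column.")
  genes <- df |> filter(.data$type == "gene")
  exons <- df |> filter(.data$type == "exon")
  if (nrow(genes) == 0L) abort("GTF contains no 'gene' features.")
  if (any(!as.character(genes$strand) %in% c("+", "-"))) {
    abort("Gene with unknown strand ('*') in GTF; strand is required to place the TSS.")
  }
  biotype <- genes[["gene_biotype"]] %||% genes[["gene_type"]] %||%
    rep("coding", nrow(genes))
  biotype <- if_else(grepl("lnc", biotype, ignore.case = TRUE), "lncRNA", "coding")
  ann <- tibble(
    gene_id = as.character(genes$gene_id),
    chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = genes$start - 1L,   # 1-based closed -> 0-based half-open
    end = as.integer(genes$end),
    biotype = biotype
  )
  ex_by_gene <- split(
    tibble(gene_id = as.character(exons$gene_id),
           start = exons$start - 1L, end = as.integer(exons$end)),
    factor(as.character(exons$gene_id), levels = ann$gene_id)
  )
  ann$exons <- unname(purrr::map(ex_by_gene, function(e) {
    e |> select("start", "end") |> arrange(.data$start)
  }))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param annotation An annotation tibble.
#' @export
validate_annotation <- function(annotation) {
  annotation <- as_tibble(annotation)
  need <- c("gene_id", "chrom", "strand", "start", "end", "biotype", "exons")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0L) abort(paste0("Annotation lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(annotation$start >= annotation$end)) {
    bad <- annotation$gene_id[which(annotation$start >= annotation$end)[1]]
    abort(paste0("Gene ", bad, " has start >= end."))
  }
  if (!all(annotation$strand %in% c("+", "-"))) abort("Strand must be '+' or '-'.")
  for (i in seq_len(nrow(annotation))) {
    e <- annotation$exons[[i]]
    if (is.null(e) || nrow(e) == 0L) {
      abort(paste0("Gene ", annotation$gene_id[i], " has no exons."))
    }
    e <- e[order(e$start), , drop = FALSE]
    if (any(e$start < annotation$start[i]) || any(e$end > annotation$end[i])) {
      abort(paste0("Gene ", annotation$gene_id[i], " has an exon outside its span."))
    }
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)])) {
      abort(paste0("Gene ", annotation$gene_id[i], " has overlapping exons."))
    }
  }
  annotation$tss <- if_else(annotation$strand == "+",
                            annotation$start, annotation$end - 1L)
  annotation |>
    select("gene_id", "chrom", "strand", "start", "end", "tss", "biotype", "exons")
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  annotation <- validate_annotation(annotation) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  lines <- character(0)
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', a$gene_id,
                     if (a$biotype == "lncRNA") "lncRNA" else "protein_coding")
    # 0-based half-open -> 1-based closed
    lines <- c(lines, paste(a$chrom, "preplateR", "gene", a$start + 1L, a$end,
                            ".", a$strand, ".", attrs, sep = "\t"))
    e <- a$exons[[1]]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, paste(a$chrom, "preplateR", "exon", e$start[j] + 1L,
                              e$end[j], ".", a$strand, ".", attrs, sep = "\t"))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

annotation_tss_granges <- function(annotation, flank) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = pmax(annotation$tss - flank, 0L) + 1L,  # to 1-based closed
      end = annotation$tss + flank
    ),
    gene_id = annotation$gene_id
  )
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}
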