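#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` disjoint gene models on the given chromosomes with a
#' minimum intergenic gap, assigns strand uniformly, gives each gene 1-3
#' exons inside its span, and labels a fraction of genes as lncRNA. The
#' default gap (12 kb) keeps adjacent TSS +/- 5 kb windows disjoint so that
#' peak emission for one gene can never contaminate a neighbour's promoter
#' window.
#'
#' @param n_genes Number of gene models.
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param frac_lncRNA Fraction of genes labelled `lncRNA`.
#' @param gene_length_range Min/max gene span in bp.
#' @param min_gap Minimum gap between consecutive gene spans in bp.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An annotation tibble (see [read_annotation()]).
#' @export
simulate_annotation <- function(n_genes,
                                chrom_sizes = c(chrSim1 = 6e7, chrSim2 = 6e7),
                                frac_lncRNA = 0.1,
                                gene_length_range = c(2000L, 20000L),
                                min_gap = 12000L,
                                seed = 1L) {
  stopifnot(n_genes >= 1L, all(chrom_sizes > 0), length(names(chrom_sizes)) > 0)
  set.seed(seed)
  # apportion genes to chromosomes proportionally to size
  n_per <- diff(round(cumsum(c(0, chrom_sizes / sum(chrom_sizes))) * n_genes))
  names(n_per) <- names(chrom_sizes)
  out <- vector("list", length(chrom_sizes))
  for (ci in seq_along(chrom_sizes)) {
    n_c <- n_per[ci]
    if (n_c == 0L) next
    len <- sample(seq(gene_length_range[1], gene_length_range[2]), n_c, replace = TRUE)
    need <- sum(len) + (n_c + 1L) * min_gap
    if (need > chrom_sizes[ci]) {
      abort(paste0("Cannot place ", n_c, " genes on ", names(chrom_sizes)[ci],
                   " (", chrom_sizes[ci], " bp) without overlap; need >= ",
                   need, " bp. Reduce density or enlarge chromosomes."))
    }
    # distribute the slack uniformly over the n_c + 1 gaps
    slack <- chrom_sizes[ci] - need
    cuts <- sort(sample.int(slack + 1L, n_c + 1L, replace = TRUE) - 1L)
    gaps <- min_gap + diff(c(0L, cuts))
    starts <- cumsum(gaps[seq_len(n_c)]) + cumsum(c(0L, len[-n_c]))
    out[[ci]] <- tibble(
      chrom = names(chrom_sizes)[ci],
      start = as.integer(starts),
      end = as.integer(starts + len)
    )
  }
  ann <- bind_rows(out)
  ann$gene_id <- sprintf("gene%05d", seq_len(nrow(ann)))
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  n_lnc <- round(frac_lncRNA * nrow(ann))
  ann$biotype <- "coding"
  if (n_lnc > 0) ann$biotype[sample.int(nrow(ann), n_lnc)] <- "lncRNA"
  ann$exons <- purrr::pmap(list(ann$start, ann$end), function(s, e) {
    n_ex <- sample(1:3, 1)
    if (n_ex == 1L) return(tibble(start = s, end = e))
    # 2*(n_ex-1) interior cut points delimit the introns
    cuts <- sort(sample(seq(s + 1L, e - 1L), 2L * (n_ex - 1L)))
    tibble(start = as.integer(c(s, cuts[seq(2L, length(cuts), by = 2L)])),
           end = as.integer(c(cuts[seq(1L, length(cuts), by = 2L)], e)))
  })
  validate_annotation(ann)
}
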