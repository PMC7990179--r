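# Shared in-code fixtures: everything is generated, nothing read from disk.

# A minimal three-gene expression table with hand-set means.
# pos means per stage are (value, value, value) with identical replicates
# unless jitter is given.
tiny_expression_table <- function(pos = list(g1 = c(6, 8, 12), g2 = c(6, 4, 12), g3 = c(0.5, 0.5, 0.5)),
                                  neg = list(g1 = c(2, 2, 3), g2 = c(3, 2, 3), g3 = c(10, 12, 14)),
                                  biotype = c("coding", "coding", "lncRNA")) {
  stages <- stage_levels()
  tab <- tibble::tibble(gene_id = names(pos), biotype = biotype)
  for (s in seq_along(stages)) {
    for (r in 1:2) {
      tab[[make_sample_key("pos", stages[s], r)]] <-
        unname(vapply(pos, function(v) v[s], 1))
      tab[[make_sample_key("neg", stages[s], r)]] <-
        unname(vapply(neg, function(v) v[s], 1))
    }
  }
  tab
}

# A two-gene annotation on one chromosome, one gene per strand.
tiny_annotation <- function() {
  tibble::tibble(
    gene_id = c("gplus", "gminus"),
    chrom = "chrT",
    strand = c("+", "-"),
    start = c(100000L, 300000L),
    end = c(110000L, 312000L),
    biotype = c("coding", "lncRNA"),
    exons = list(
      tibble::tibble(start = c(100000L, 105000L), end = c(102000L, 110000L)),
      tibble::tibble(start = 300000L, end = 312000L)
    )
  ) |> validate_annotation()
}

# Brute-force all-pairs TSS/distal overlap oracle (quadratic, obviously
# correct), used to check the interval-join implementation.
brute_force_binding <- function(peaks, annotation, tss_window, distal_window) {
  out <- list()
  groups <- unique(peaks[, c("mark", "sample")])
  for (g in seq_len(nrow(groups))) {
    p <- peaks[peaks$mark == groups$mark[g] & peaks$sample == groups$sample[g], ]
    for (i in seq_len(nrow(annotation))) {
      tss <- annotation$tss[i]
      same <- p$chrom == annotation$chrom[i]
      ov_tss <- same & p$start < tss + tss_window & p$end > tss - tss_window
      ov_dist <- same & p$start < tss + distal_window & p$end > tss - distal_window
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = annotation$gene_id[i],
        mark = groups$mark[g], sample = groups$sample[g],
        tss_bound = any(ov_tss),
        distal_bound = any(ov_dist & !ov_tss)
      )
    }
  }
  dplyr::bind_rows(out)
}
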