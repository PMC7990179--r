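#' Overlap of a query gene set with a reference set
#'
#' @param reference Non-empty character vector (the denominator).
#' @param query Character vector.
#' @return A tibble `n_reference`, `n_intersect`, `pct_of_reference`
#'   (percentage on the 0-100 scale).
#' @export
#' @examples
#' set_overlap_stats(c("a", "b", "c", "d"), c("b", "d", "e"))
set_overlap_stats <- function(reference, query) {
  reference <- unique(reference)
  if (length(reference) == 0L) abort("Empty reference set.")
  n_int <- length(intersect(reference, unique(query)))
  tibble(n_reference = length(reference), n_intersect = n_int,
         pct_of_reference = 100 * n_int / length(reference))
}

#' Distribution of transcription-factor targets across pseudotime states
#'
#' Counts how many of a TF's target genes fall into each (disjoint)
#' state gene set, e.g. how many targets are early-state versus
#' intermediate-state genes.
#'
#' @param targets Character vector of target gene ids.
#' @param state_gene_sets Named list of disjoint character vectors, one
#'   per state.
#' @return A tibble `state`, `n_state_genes`, `n_targets`,
#'   `pct_of_state`.
#' @export
tf_target_distribution <- function(targets, state_gene_sets) {
  sets <- purrr::map(state_gene_sets, unique)
  all_members <- unlist(sets)
  if (anyDuplicated(all_members)) {
    abort("State gene sets must be disjoint.")
  }
  purrr::imap(sets, function(members, nm) {
    n_int <- length(intersect(targets, members))
    tibble(state = nm, n_state_genes = length(members), n_targets = n_int,
           pct_of_state = if (length(members) > 0) 100 * n_int / length(members) else 0)
  }) |>
    bind_rows()
}

#' Cross-tabulate bulk temporal classes against single-cell states
#'
#' For every (temporal class, pseudotime state) pair: the intersection of
#' the class's genes with the state's gene set and the percentage of the
#' class covered — the bridge between the bulk trajectory classes and the
#' single-cell state groups.
#'
#' @param classes Tibble `gene_id`, `class` (from [classify_temporal()]).
#' @param state_sets Named list of character vectors (state -> genes),
#'   e.g. top-expressed genes per state.
#' @return A tibble `class`, `state`, `n_class`, `n_intersect`,
#'   `pct_of_class`, covering observed classes x states.
#' @export
integrate_bulk_sc <- function(classes, state_sets) {
  by_class <- split(classes$gene_id, classes$class)
  out <- list()
  for (cl in names(by_class)) {
    for (st in names(state_sets)) {
      ov <- set_overlap_stats(by_class[[cl]], state_sets[[st]])
      out[[paste(cl, st)]] <- tibble(
        class = cl, state = st, n_class = ov$n_reference,
        n_intersect = ov$n_intersect, pct_of_class = ov$pct_of_reference)
    }
  }
  bind_rows(out) |> arrange(.data$class, .data$state)
}
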