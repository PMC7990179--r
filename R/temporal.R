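#' Trinarize a pos/neg expression ratio
#'
#' The trajectory alphabet: a ratio of at least 2 is "up" (enriched in the
#' reporter-positive population), a ratio in [1, 2) is "unchanged", and a
#' ratio below 1 is "down". Both boundaries are inclusive on the upper
#' state (2 -> up, 1 -> unchanged). `Inf` maps to "up".
#'
#' @param ratio Numeric vector of non-negative ratios (may contain `Inf`).
#' @return Character vector over `{"up", "unchanged", "down"}`.
#' @export
#' @examples
#' trinarize(c(2.5, 1, 0.4, Inf))
trinarize <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) {
    abort("Ratios must be non-negative and defined.")
  }
  dplyr::case_when(ratio >= 2 ~ "up",
                   ratio >= 1 ~ "unchanged",
                   .default = "down")
}

trinary_levels <- function() c("up", "unchanged", "down")

# render a state triple as a class label, e.g. "E11up-E13unchange-E15down"
class_label <- function(states) {
  tok <- c(up = "up", unchanged = "unchange", down = "down")[states]
  paste0(c("E11", "E13", "E15"), tok, collapse = "-")
}

#' The 27-class temporal label space
#'
#' All ordered triples of trinary states over the three stages, in
#' deterministic lexicographic order with `up < unchanged < down` within
#' each stage.
#'
#' @return A tibble with `class` (label) and `states` (list-column of
#'   length-3 character vectors), 27 rows.
#' @export
enumerate_class_space <- function() {
  lv <- trinary_levels()
  grid <- expand.grid(s3 = lv, s2 = lv, s1 = lv,
                      stringsAsFactors = FALSE)[, 3:1]
  states <- purrr::pmap(grid, function(s1, s2, s3) c(s1, s2, s3))
  tibble(class = purrr::map_chr(states, class_label), states = states)
}

#' Assign each gene its temporal class
#'
#' Component-wise trinarization of the three per-stage ratios.
#'
#' @param ratios Ratio tibble from [compute_stage_ratio()] covering all
#'   three stages.
#' @return A tibble `gene_id`, `class`, plus the three per-stage states
#'   `state_E11.5`, `state_E13.5`, `state_E15.5`.
#' @export
classify_temporal <- function(ratios) {
  if (!setequal(unique(ratios$stage), stage_levels())) {
    abort("classify_temporal() needs ratios at all three stages.")
  }
  wide <- ratios |>
    select("gene_id", "stage", "ratio") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "ratio")
  states <- purrr::map(stage_levels(), ~ trinarize(wide[[.x]]))
  out <- tibble(gene_id = wide$gene_id)
  for (i in 1:3) out[[paste0("state_", stage_levels()[i])]] <- states[[i]]
  out$class <- purrr::pmap_chr(
    list(states[[1]], states[[2]], states[[3]]),
    function(a, b, c) class_label(c(a, b, c)))
  out |> select("gene_id", "class", dplyr::starts_with("state_"))
}

#' Count genes per temporal class
#'
#' @param classes Tibble from [classify_temporal()].
#' @param universe Optional character vector restricting the counted genes
#'   (e.g. the DEG universe); default all genes in `classes`.
#' @return A tibble `class`, `n` over all 27 classes (zero counts
#'   included), rows in the lexicographic class order.
#' @export
tabulate_classes <- function(classes, universe = NULL) {
  if (!is.null(universe)) classes <- classes |> filter(.data$gene_id %in% universe)
  space <- enumerate_class_space()$class
  counts <- table(factor(classes$class, levels = space))
  tibble(class = space, n = as.integer(counts))
}

#' Default trajectory-group archetypes
#'
#' The six exemplar classes used to group the temporal space: consistently
#' enriched, consistently depleted, early-enriched-then-falling,
#' falling-then-recovering, consistently-falling-with-plateau, and flat.
#'
#' @return Character vector of six class labels.
#' @export
default_archetypes <- function() {
  c(class_label(c("up", "up", "up")),
    class_label(c("down", "down", "down")),
    class_label(c("up", "unchanged", "down")),
    class_label(c("down", "unchanged", "up")),
    class_label(c("down", "unchanged", "down")),
    class_label(c("unchanged", "unchanged", "unchanged")))
}

#' Group temporal classes by nearest archetype
#'
#' Each class is assigned to the archetype with minimum Hamming distance
#' over the three state symbols; ties go to the earlier archetype in the
#' list. An explicit `override` map (named character vector class ->
#' group) takes precedence. The grouping is a declared heuristic: the
#' biological six-group interpretation names exemplars, not a full
#' mapping.
#'
#' @param classes Tibble with `gene_id` and `class` (from
#'   [classify_temporal()]), or a character vector of class labels.
#' @param archetypes Character vector of class labels (non-empty).
#' @param override Optional named character vector mapping class label ->
#'   group label.
#' @return Input tibble with a `group` column appended (or a character
#'   vector if `classes` was one).
#' @export
assign_groups <- function(classes, archetypes = default_archetypes(),
                          override = NULL) {
  if (length(archetypes) == 0L) abort("archetypes must be non-empty.")
  space <- enumerate_class_space()
  arch_states <- space$states[match(archetypes, space$class)]
  if (any(vapply(arch_states, is.null, TRUE))) abort("Unknown archetype label.")
  lookup <- vapply(space$states, function(st) {
    d <- vapply(arch_states, function(a) sum(st != a), 0L)
    archetypes[which.min(d)]
  }, "")
  names(lookup) <- space$class
  if (!is.null(override)) lookup[names(override)] <- override
  if (is.character(classes)) return(unname(lookup[classes]))
  classes |> mutate(group = unname(lookup[.data$class]))
}

#' Expression-trend category of the positive population
#'
#' Classifies the three positive-population stage means: `increasing` when
#' strictly monotone up; `low_decreasing` when all three means are below 1
#' FPKM and strictly monotone down; `low_stable` when all below 1 but not
#' monotone down; `other` otherwise. A relative tolerance can soften the
#' strict monotonicity (default 0).
#'
#' @param ratios Ratio tibble from [compute_stage_ratio()] (its `mean_pos`
#'   column is used), covering all three stages.
#' @param low_fpkm FPKM ceiling defining "lowly expressed".
#' @param tolerance Relative tolerance on the monotone comparisons.
#' @return A tibble `gene_id`, `trend`.
#' @export
trend_category <- function(ratios, low_fpkm = 1, tolerance = 0) {
  if (!setequal(unique(ratios$stage), stage_levels())) {
    abort("trend_category() needs all three stages.")
  }
  wide <- ratios |>
    select("gene_id", "stage", "mean_pos") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "mean_pos")
  m <- as.matrix(wide[, stage_levels()])
  if (tolerance > 0) {
    up <- m[, 2] >= m[, 1] * (1 - tolerance) & m[, 3] >= m[, 2] * (1 - tolerance) &
      m[, 3] > m[, 1]
    down <- m[, 2] <= m[, 1] * (1 + tolerance) & m[, 3] <= m[, 2] * (1 + tolerance) &
      m[, 3] < m[, 1]
  } else {
    up <- m[, 2] > m[, 1] & m[, 3] > m[, 2]
    down <- m[, 2] < m[, 1] & m[, 3] < m[, 2]
  }
  low <- rowSums(m < low_fpkm) == 3L
  tibble(
    gene_id = wide$gene_id,
    trend = dplyr::case_when(
      up ~ "increasing",
      low & down ~ "low_decreasing",
      low ~ "low_stable",
      .default = "other"
    )
  )
}
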