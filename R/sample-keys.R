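#' Developmental stages and FACS populations
#'
#' The pipeline covers three embryonic cortical stages and two FACS-sorted
#' populations (reporter-positive preplate/Cajal-Retzius cells, `pos`, and
#' reporter-negative progenitors, `neg`). Stages carry a total order
#' E11.5 < E13.5 < E15.5.
#'
#' @return `stage_levels()` returns the ordered character vector of stage
#'   names; `population_levels()` the two population codes.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("E11.5", "E13.5", "E15.5")

#' @rdname stage_levels
#' @export
population_levels <- function() c("pos", "neg")

assert_stage <- function(stage) {
  if (!all(stage %in% stage_levels())) {
    abort(paste0(
      "Unknown stage(s): ", paste(setdiff(stage, stage_levels()), collapse = ", "),
      ". Stages must be one of ", paste(stage_levels(), collapse = ", "), "."
    ))
  }
  stage
}

#' Parse sample column names into population / stage / replicate keys
#'
#' Sample columns follow the grammar `<pop>_<stage>_<rep>` with
#' `pop` in `pos`/`neg`, e.g. `"pos_E11.5_1"`. Columns that do not match are
#' returned with `NA` fields so callers can report them.
#'
#' @param x Character vector of column names.
#' @return A tibble with columns `column`, `population`, `stage`,
#'   `replicate` (integer); non-matching names have `NA` key fields.
#' @export
#' @examples
#' parse_sample_key(c("pos_E11.5_1", "neg_E15.5_2", "gene_id"))
parse_sample_key <- function(x) {
  m <- stringr::str_match(x, "^(pos|neg)_(E11\\.5|E13\\.5|E15\\.5)_([0-9]+)$")
  tibble(
    column = x,
    population = m[, 2],
    stage = m[, 3],
    replicate = as.integer(m[, 4])
  )
}

#' @rdname parse_sample_key
#' @param population,stage,replicate Vectors recycled to a common length.
#' @export
make_sample_key <- function(population, stage, replicate) {
  stopifnot(all(population %in% population_levels()))
  assert_stage(stage)
  paste(population, stage, replicate, sep = "_")
}

# sample key columns of an expression table, with a hard error when none found
sample_key_info <- function(table) {
  keys <- parse_sample_key(names(table))
  keys <- keys[!is.na(keys$population), , drop = FALSE]
  if (nrow(keys) == 0L) {
    abort("No sample columns of the form <pop>_<stage>_<rep> found in the table.")
  }
  keys
}
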