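# broom-style accessors for result objects.

#' Tidy dynamics calls
#'
#' @param x A `dynamics_calls` tibble from [classify_dynamics()].
#' @param ... Unused.
#' @return One row per unit with the `expressing` list-column flattened to a
#'   comma-joined string.
#' @export
tidy.dynamics_calls <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                expressing = purrr::map_chr(.data$expressing, paste, collapse = ","))
}

#' One-row summary of dynamics calls
#'
#' @inheritParams tidy.dynamics_calls
#' @return Tibble with unit counts per label.
#' @export
glance.dynamics_calls <- function(x, ...) {
  tibble::tibble(n_units = nrow(x),
                 n_dynamic = sum(x$label == "dynamic"),
                 n_constitutive = sum(x$label == "constitutive"),
                 n_silent = sum(x$label == "silent"))
}

#' Tidy candidate-TF rankings
#'
#' @param x A `candidate_tfs` tibble.
#' @param ... Unused.
#' @return The ranking as a plain tibble.
#' @export
tidy.candidate_tfs <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a TF ranking
#'
#' @inheritParams tidy.candidate_tfs
#' @return Tibble with candidate counts and the top hit.
#' @export
glance.candidate_tfs <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x),
                 top_tf = if (nrow(x) > 0) x$tf[1] else NA_character_,
                 max_abs_log2fc = if (nrow(x) > 0) max(abs(x$log2fc)) else NA_real_)
}

#' Tidy a pipeline run
#'
#' @param x A `pritx_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The elements tibble (the run's central product).
#' @export
tidy.pritx_run <- function(x, ...) tibble::as_tibble(x$elements)

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.pritx_run
#' @return Counts of units, elements, motif hits and candidates.
#' @export
glance.pritx_run <- function(x, ...) {
  tibble::tibble(n_units = nrow(x$units),
                 n_dynamic = sum(x$dynamics$label == "dynamic"),
                 n_elements = nrow(x$elements),
                 n_motif_hits = nrow(x$motif_hits),
                 n_conserved_hits = sum(x$motif_hits$conserved),
                 n_candidates = nrow(x$candidates))
}
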