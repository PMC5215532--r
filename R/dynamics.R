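#' Classify transcription units as dynamic, constitutive or silent
#'
#' Operationalizes the silent-then-expressed versus always-on distinction as
#' a pseudocounted max/min fold statistic over an ordered sample series:
#' `log2_range = log2((max + pseudocount) / (min + pseudocount))`. A unit is
#' `dynamic` when `log2_range >= log2(fold_threshold)` and its maximum
#' abundance reaches `expression_floor`; `constitutive` when below the fold
#' threshold but expressed; `silent` when no sample reaches the floor. The
#' `expressing` set (samples at or above the floor) drives downstream
#' regulatory-element colocalization.
#'
#' @param abundances Tibble with columns `unit_id`, `sample_id`, `abundance`
#'   (>= 2 samples per unit).
#' @param pseudocount Positive pseudocount added to max and min.
#' @param fold_threshold Fold change (> 1) separating dynamic from
#'   constitutive.
#' @param expression_floor Abundance a sample must reach to count as
#'   expressing (same units as `abundance`, RPKM-like).
#' @return A `dynamics_calls` tibble: `unit_id`, `log2_range`, `label`,
#'   `expressing` (list-column of sample ids), `n_expressing`, `max_abundance`.
#' @examples
#' ab <- tibble::tibble(unit_id = "TU01",
#'                      sample_id = c("ESC", "iPSC", "PSC_NPC", "tissue_NPC"),
#'                      abundance = c(0, 0, 0, 10))
#' classify_dynamics(ab)
#' @export
classify_dynamics <- function(abundances, pseudocount = 0.5, fold_threshold = 4,
                              expression_floor = 1) {
  stopifnot(is.data.frame(abundances),
            all(c("unit_id", "sample_id", "abundance") %in% names(abundances)))
  stopifnot(pseudocount > 0, fold_threshold > 1, expression_floor >= 0)
  if (any(!is.finite(abundances$abundance)) || any(abundances$abundance < 0)) {
    stop("classify_dynamics: abundances must be finite and >= 0", call. = FALSE)
  }
  n_per_unit <- table(abundances$unit_id)
  if (any(n_per_unit < 2)) {
    stop("classify_dynamics: every unit needs >= 2 samples", call. = FALSE)
  }
  out <- abundances |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      log2_range = log2((max(.data$abundance) + pseudocount) /
                          (min(.data$abundance) + pseudocount)),
      max_abundance = max(.data$abundance),
      expressing = list(sort(.data$sample_id[.data$abundance >= expression_floor],
                             method = "radix")),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$max_abundance < expression_floor ~ "silent",
        .data$log2_range >= log2(fold_threshold) ~ "dynamic",
        TRUE ~ "constitutive"
      ),
      n_expressing = lengths(.data$expressing)
    ) |>
    dplyr::select("unit_id", "log2_range", "label", "expressing",
                  "n_expressing", "max_abundance")
  class(out) <- c("dynamics_calls", class(out))
  out
}

#' First switch-on index in an ordered series
#'
#' Given a logical on/off series in differentiation order, returns the
#' 0-based index of the earliest position where the condition first holds,
#' provided it held at no earlier position. Returns `NA` when the condition
#' never holds or already holds at the first position (always on).
#'
#' @param on Logical vector in sample order (or a numeric vector with
#'   `floor`, compared as `>= floor`).
#' @param floor Expression floor applied when `on` is numeric.
#' @return Integer 0-based transition index, or `NA_integer_`.
#' @examples
#' order_transitions(c(FALSE, FALSE, TRUE)) # 2
#' order_transitions(c(TRUE, TRUE))         # NA: always on
#' @export
order_transitions <- function(on, floor = 1) {
  if (is.numeric(on)) on <- on >= floor
  stopifnot(is.logical(on), length(on) >= 1, !anyNA(on))
  if (!any(on) || on[1]) return(NA_integer_)
  which(on)[1] - 1L
}
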