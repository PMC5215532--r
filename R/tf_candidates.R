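# TF nomination: ChIP binding over candidate elements crossed with
# differential expression between two named conditions.

#' Overlap TF ChIP peaks with candidate elements
#'
#' @param elements Element tibble with `element_id`, `chrom`, `start`, `end`.
#' @param tf_peaks Peak tibble with `chrom`, `start`, `end`, `tf` (the TF
#'   gene label).
#' @return One row per (tf, element) with >= 1 bp overlap: `tf`,
#'   `element_id`, `overlap_bp` (summed intersection), `n_peaks`.
#' @export
overlap_tf_peaks <- function(elements, tf_peaks) {
  stopifnot("element_id" %in% names(elements), "tf" %in% names(tf_peaks))
  validate_intervals(elements, "overlap_tf_peaks(elements)")
  if (nrow(tf_peaks) == 0 || nrow(elements) == 0) {
    return(tibble::tibble(tf = character(), element_id = character(),
                          overlap_bp = integer(), n_peaks = integer()))
  }
  validate_intervals(tf_peaks, "overlap_tf_peaks(tf_peaks)")
  dplyr::inner_join(
    dplyr::rename(tf_peaks, pstart = "start", pend = "end"),
    elements[, c("element_id", "chrom", "start", "end")],
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::mutate(ov = pmin(.data$pend, .data$end) - pmax(.data$pstart, .data$start)) |>
    dplyr::filter(.data$ov >= 1) |>
    dplyr::group_by(.data$tf, .data$element_id) |>
    dplyr::summarise(overlap_bp = as.integer(sum(.data$ov)),
                     n_peaks = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$tf, .data$element_id)
}

#' Log2 expression contrast between two conditions
#'
#' Per gene, `log2((mean_b + pseudocount) / (mean_a + pseudocount))`,
#' reported b over a (positive = higher in condition b).
#'
#' @param table Expression tibble from [read_expression_tsv()] (`gene`
#'   column plus one column per sample).
#' @param cond_a,cond_b Non-empty, disjoint sample-label sets, all present
#'   in `table`.
#' @param pseudocount Positive pseudocount.
#' @return Tibble `gene`, `mean_a`, `mean_b`, `log2fc`.
#' @export
expression_contrast <- function(table, cond_a, cond_b, pseudocount = 1) {
  stopifnot(length(cond_a) >= 1, length(cond_b) >= 1, pseudocount > 0)
  if (length(intersect(cond_a, cond_b)) > 0) {
    stop("expression_contrast: conditions must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(c(cond_a, cond_b), names(table))
  if (length(unknown) > 0) {
    stop(sprintf("expression_contrast: unknown sample label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    gene = table$gene,
    mean_a = rowMeans(table[, cond_a, drop = FALSE]),
    mean_b = rowMeans(table[, cond_b, drop = FALSE])
  ) |>
    dplyr::mutate(log2fc = log2((.data$mean_b + pseudocount) /
                                  (.data$mean_a + pseudocount)))
}

#' Rank candidate regulator TFs
#'
#' Candidates are the TFs with at least one binding record, absolute log2
#' fold change at or above `min_abs_log2fc`, mean expression in the
#' reference (b) condition at or above `min_expression` (actively
#' transcribed), and — when `family_prefixes` is given — a gene label
#' starting with one of the prefixes (e.g. `"FOX"`). Sorted by |log2FC|
#' descending, ties broken by gene label ascending; ranks 1..n.
#'
#' @param binding Output of [overlap_tf_peaks()].
#' @param contrasts Output of [expression_contrast()].
#' @param min_abs_log2fc Differential-expression threshold.
#' @param family_prefixes Optional character vector of gene-label prefixes.
#' @param min_expression Expression floor in the reference condition
#'   (`mean_b`); ignored when `contrasts` lacks `mean_b`.
#' @return A `candidate_tfs` tibble: `rank`, `tf`, `log2fc`, `overlap_bp`,
#'   `n_peaks`, `n_elements`.
#' @export
candidate_tfs <- function(binding, contrasts, min_abs_log2fc = 1.0,
                          family_prefixes = NULL, min_expression = 1.0) {
  stopifnot(min_abs_log2fc >= 0)
  bound <- binding |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(overlap_bp = sum(.data$overlap_bp),
                     n_peaks = sum(.data$n_peaks),
                     n_elements = dplyr::n_distinct(.data$element_id),
                     .groups = "drop")
  de <- dplyr::filter(contrasts, abs(.data$log2fc) >= min_abs_log2fc)
  if ("mean_b" %in% names(de)) {
    de <- dplyr::filter(de, .data$mean_b >= min_expression)
  }
  out <- dplyr::inner_join(bound, de, by = c(tf = "gene"))
  if (!is.null(family_prefixes) && length(family_prefixes) > 0) {
    pat <- paste0("^(", paste(family_prefixes, collapse = "|"), ")")
    out <- dplyr::filter(out, stringr::str_detect(.data$tf, pat))
  }
  out <- out |>
    dplyr::arrange(dplyr::desc(abs(.data$log2fc)), .data$tf) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "tf", "log2fc", "overlap_bp", "n_peaks", "n_elements")
  class(out) <- c("candidate_tfs", class(out))
  out
}
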