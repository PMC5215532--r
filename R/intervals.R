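#' Construct a genomic-interval tibble
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' matching BED/bedGraph. Conversion to 1-based closed coordinates happens
#' only at the GFF3 boundary ([write_gff3()]).
#'
#' @param chrom Chromosome names (character).
#' @param start,end Integer-like coordinates, `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` (recycled).
#' @param name Optional labels (recycled; `NA` allowed).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `name`.
#' @examples
#' gi("chr1", 100, 200, "+", "x")
#' @export
gi <- function(chrom, start, end, strand = ".", name = NA_character_) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(round(as.numeric(start))),
    end = as.integer(round(as.numeric(end))),
    strand = as.character(strand),
    name = as.character(name)
  )
  validate_intervals(x)
  x
}

#' Validate an interval tibble
#'
#' Checks the coordinate invariants: non-empty `chrom`, integer
#' `0 <= start < end`, `strand` in `{+, -, .}`.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param context Label used in error messages.
#' @return `x`, invisibly. Errors on the first violated invariant.
#' @export
validate_intervals <- function(x, context = "interval") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing columns: %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | x$chrom == "")) {
    stop(sprintf("%s: empty chromosome name", context), call. = FALSE)
  }
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    stop(sprintf("%s: non-finite coordinates", context), call. = FALSE)
  }
  if (any(x$start < 0)) {
    stop(sprintf("%s: negative start", context), call. = FALSE)
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    stop(sprintf("%s: start >= end at record %d (%s:%d-%d)", context, bad[1],
                 x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]), call. = FALSE)
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop(sprintf("%s: strand must be one of +, -, .", context), call. = FALSE)
  }
  invisible(x)
}

# tibble of intervals on ONE chromosome -> IRanges
.to_ir <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# IRanges -> tibble of intervals (chrom attached back)
.from_ir <- function(ir, chrom) {
  if (length(ir) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  tibble::tibble(chrom = chrom,
                 start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir))
}

#' Merge overlapping or near-adjacent intervals
#'
#' Union of intervals per chromosome (and per strand when a `strand` column
#' is present), additionally bridging gaps of at most `max_gap` bases.
#'
#' @param x Interval tibble.
#' @param max_gap Non-negative gap width (bp) to bridge; 0 merges only
#'   overlapping/bookended intervals.
#' @return Interval tibble sorted by (chrom, start), strand retained when
#'   present in the input.
#' @export
merge_intervals <- function(x, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  validate_intervals(x, "merge_intervals")
  if (nrow(x) == 0) return(dplyr::as_tibble(x))
  has_strand <- "strand" %in% names(x)
  keys <- if (has_strand) c("chrom", "strand") else "chrom"
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, k) {
      ir <- IRanges::reduce(.to_ir(g), min.gapwidth = max_gap + 1L)
      tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(dplyr::any_of(c("chrom", "start", "end", "strand")))
}

#' Base-wise intersection of two interval sets
#'
#' @param a,b Interval tibbles (strand is ignored; intersect per chromosome).
#' @return Interval tibble of the intersected bases, merged and sorted.
#' @export
intersect_intervals <- function(a, b) {
  validate_intervals(a, "intersect_intervals(a)")
  validate_intervals(b, "intersect_intervals(b)")
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- purrr::map(chroms, function(ch) {
    ir <- IRanges::intersect(
      IRanges::reduce(.to_ir(a[a$chrom == ch, , drop = FALSE])),
      IRanges::reduce(.to_ir(b[b$chrom == ch, , drop = FALSE]))
    )
    .from_ir(ir, ch)
  })
  out <- c(list(tibble::tibble(chrom = character(), start = integer(),
                               end = integer())), out)
  dplyr::bind_rows(out) |> dplyr::arrange(.data$chrom, .data$start)
}

# Bases covered by >= min_count of the interval sets in `sets`
# (a list of interval tibbles, each first reduced), on one chromosome set.
.support_intervals <- function(sets, min_count) {
  sets <- purrr::keep(sets, ~ nrow(.x) > 0)
  if (length(sets) == 0 || min_count > length(sets)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  chroms <- unique(unlist(purrr::map(sets, ~ unique(.x$chrom))))
  out <- purrr::map(chroms, function(ch) {
    irl <- purrr::map(sets, ~ IRanges::reduce(.to_ir(.x[.x$chrom == ch, , drop = FALSE])))
    w <- max(purrr::map_int(irl, ~ if (length(.x) == 0) 0L else max(IRanges::end(.x))))
    cov <- Reduce(`+`, purrr::map(irl, ~ IRanges::coverage(.x, width = w)))
    sl <- IRanges::slice(cov, lower = min_count, rangesOnly = TRUE)
    .from_ir(sl, ch)
  })
  out <- c(list(tibble::tibble(chrom = character(), start = integer(),
                               end = integer())), out)
  dplyr::bind_rows(out) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Summed pairwise overlap between two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Total overlapping bases between the union of `a` and the union of
#'   `b` (strand-blind).
#' @export
overlap_width <- function(a, b) {
  ov <- intersect_intervals(a, b)
  if (nrow(ov) == 0) return(0L)
  sum(ov$end - ov$start)
}
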