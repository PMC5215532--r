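#' Build a coverage track
#'
#' A coverage track is a run-length encoding of per-base signal for one
#' sample and strand: non-overlapping, sorted runs each carrying a finite
#' value >= 0. Querying a base outside every run yields 0.
#'
#' @param runs Tibble with columns `chrom`, `start`, `end`, `value`.
#' @param sample_id Sample label.
#' @param strand `"+"`, `"-"` or `"."` (bedGraph carries no strand, so the
#'   strand is an explicit track attribute supplied by the caller/config).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(runs, sample_id = "sample", strand = ".") {
  stopifnot(is.data.frame(runs), all(c("chrom", "start", "end", "value") %in% names(runs)))
  stopifnot(strand %in% c("+", "-", "."), nzchar(sample_id))
  validate_intervals(runs, "coverage_track")
  if (nrow(runs) > 0) {
    if (any(!is.finite(runs$value)) || any(runs$value < 0)) {
      stop("coverage_track: values must be finite and >= 0", call. = FALSE)
    }
    runs <- dplyr::arrange(runs, .data$chrom, .data$start)
    ov <- runs |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(prev_end = dplyr::lag(.data$end, default = -1L)) |>
      dplyr::ungroup()
    if (any(ov$start < ov$prev_end)) {
      bad <- which(ov$start < ov$prev_end)[1]
      stop(sprintf("coverage_track: overlapping runs at %s:%d", runs$chrom[bad],
                   runs$start[bad]), call. = FALSE)
    }
    runs <- .coalesce_runs(runs)
  }
  structure(
    list(sample_id = sample_id, strand = strand,
         runs = dplyr::as_tibble(runs[, c("chrom", "start", "end", "value")])),
    class = "coverage_track"
  )
}

# merge bookended runs with equal value
.coalesce_runs <- function(runs) {
  runs |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      new_run = dplyr::row_number() == 1L |
        .data$start != dplyr::lag(.data$end, default = -1L) |
        .data$value != dplyr::lag(.data$value, default = NA_real_),
      run_id = cumsum(.data$new_run)
    ) |>
    dplyr::group_by(.data$chrom, .data$run_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     value = .data$value[1], .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "value")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> sample=%s strand=%s runs=%d\n",
              x$sample_id, x$strand, nrow(x$runs)))
  print(utils::head(x$runs, 5))
  invisible(x)
}

#' Per-base values of a track over a region
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome.
#' @param start,end 0-based half-open region.
#' @return Numeric vector of length `end - start`; uncovered bases are 0.
#' @export
track_values <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"), end > start)
  v <- numeric(end - start)
  r <- track$runs[track$runs$chrom == chrom &
                    track$runs$end > start & track$runs$start < end, , drop = FALSE]
  if (nrow(r) > 0) {
    for (i in seq_len(nrow(r))) {
      a <- max(r$start[i], start) - start + 1L
      b <- min(r$end[i], end) - start
      v[a:b] <- r$value[i]
    }
  }
  v
}

#' Sum of per-base values over a region
#'
#' Computed from run overlaps without materializing bases.
#'
#' @inheritParams track_values
#' @return Scalar sum (uncovered bases contribute 0).
#' @export
track_sum <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"), end > start)
  r <- track$runs[track$runs$chrom == chrom &
                    track$runs$end > start & track$runs$start < end, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  sum((pmin(r$end, end) - pmax(r$start, start)) * r$value)
}

#' Mean per-base value over a region
#'
#' @inheritParams track_values
#' @return `track_sum(...) / (end - start)`.
#' @export
track_mean <- function(track, chrom, start, end) {
  track_sum(track, chrom, start, end) / (end - start)
}
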