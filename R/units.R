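#' Call nascent transcription units from a coverage track
#'
#' Nascent (chromatin-associated) RNA coverage over a pri-miRNA locus is
#' long, sparse and strand-specific. Units are maximal runs of bases with
#' coverage at or above `min_cov`, after bridging sub-threshold gaps of at
#' most `max_gap` bases (single pass: threshold runs, then merge), retained
#' when at least `min_len` long.
#'
#' @param track A [coverage_track()] with strand `"+"` or `"-"`.
#' @param min_cov Coverage threshold (> 0) a base must reach.
#' @param max_gap Largest sub-threshold gap (bp) bridged between runs.
#' @param min_len Minimum retained unit length (bp).
#' @return Tibble of units: `chrom`, `start`, `end`, `strand`, `sample_id`,
#'   `mean_cov` (mean coverage over the unit), sorted and pairwise disjoint
#'   per (chrom, strand).
#' @examples
#' tr <- coverage_track(tibble::tibble(chrom = "chr1", start = 0L,
#'                                     end = 1000L, value = 5), "s1", "+")
#' call_units(tr, min_cov = 1, max_gap = 100, min_len = 200)
#' @export
call_units <- function(track, min_cov = 1.0, max_gap = 500L, min_len = 1000L) {
  stopifnot(inherits(track, "coverage_track"))
  stopifnot(min_cov > 0, max_gap >= 0, min_len >= 1)
  if (!track$strand %in% c("+", "-")) {
    stop("call_units: track must carry an explicit strand (+ or -)", call. = FALSE)
  }
  above <- track$runs[track$runs$value >= min_cov, c("chrom", "start", "end")]
  if (nrow(above) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          strand = character(), sample_id = character(),
                          mean_cov = numeric()))
  }
  units <- merge_intervals(above, max_gap = max_gap)
  units <- units[units$end - units$start >= min_len, , drop = FALSE]
  if (nrow(units) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          strand = character(), sample_id = character(),
                          mean_cov = numeric()))
  }
  units$strand <- track$strand
  units$sample_id <- track$sample_id
  units$mean_cov <- purrr::pmap_dbl(
    units[, c("chrom", "start", "end")],
    function(chrom, start, end) track_mean(track, chrom, start, end)
  )
  dplyr::arrange(units, .data$chrom, .data$start)
}

#' Merge per-sample unit calls into locus-level units
#'
#' One annotated transcript per locus across samples: per-sample calls are
#' unioned (not intersected, so silent samples never erase a unit) per
#' chromosome and strand, and stable `unit_id`s are assigned in coordinate
#' order.
#'
#' @param per_sample_units Tibble as returned by [call_units()] (rows from
#'   several samples may be bound together).
#' @return Tibble of locus units: `unit_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
merge_unit_calls <- function(per_sample_units) {
  if (nrow(per_sample_units) == 0) {
    return(tibble::tibble(unit_id = character(), chrom = character(),
                          start = integer(), end = integer(), strand = character()))
  }
  validate_intervals(per_sample_units, "merge_unit_calls")
  merged <- merge_intervals(
    per_sample_units[, c("chrom", "start", "end", "strand")], max_gap = 0L
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
  merged$unit_id <- sprintf("TU%02d", seq_len(nrow(merged)))
  merged[, c("unit_id", "chrom", "start", "end", "strand")]
}

#' Assign mature-miRNA loci to transcription units
#'
#' A locus joins a unit iff it is fully contained in the unit interval and
#' strand-matched; since units are disjoint per (chrom, strand) a locus joins
#' at most one unit. Units with >= 2 members are flagged polycistronic.
#'
#' @param units Unit tibble with `unit_id`, `chrom`, `start`, `end`, `strand`.
#' @param mirna_loci Stranded interval tibble of mature-miRNA loci.
#' @return A list with `assignments` (one row per assigned locus:
#'   `unit_id`, locus coordinates and `name`), `polycistrons` (per unit:
#'   `n_members`, `polycistronic` flag, comma-joined `members`), and
#'   `unassigned` (loci contained in no unit).
#' @export
assign_mirnas <- function(units, mirna_loci) {
  validate_intervals(mirna_loci, "assign_mirnas")
  if (nrow(mirna_loci) > 0 && !all(mirna_loci$strand %in% c("+", "-"))) {
    stop("assign_mirnas: miRNA loci must be stranded", call. = FALSE)
  }
  if (nrow(mirna_loci) == 0 || nrow(units) == 0) {
    empty <- tibble::tibble(unit_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), name = character())
    return(list(assignments = empty,
                polycistrons = tibble::tibble(unit_id = character(),
                                              n_members = integer(),
                                              polycistronic = logical(),
                                              members = character()),
                unassigned = mirna_loci))
  }
  hit <- dplyr::inner_join(
    dplyr::mutate(mirna_loci, .locus = dplyr::row_number()),
    dplyr::rename(units, ustart = "start", uend = "end"),
    by = c("chrom", "strand"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$start >= .data$ustart, .data$end <= .data$uend)
  assignments <- hit[, c("unit_id", "chrom", "start", "end", "strand", "name")] |>
    dplyr::arrange(.data$unit_id, .data$start)
  polycistrons <- assignments |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(n_members = dplyr::n(),
                     members = paste(.data$name, collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(polycistronic = .data$n_members >= 2L) |>
    dplyr::select("unit_id", "n_members", "polycistronic", "members")
  unassigned <- mirna_loci[!seq_len(nrow(mirna_loci)) %in% hit$.locus, , drop = FALSE]
  list(assignments = assignments, polycistrons = polycistrons,
       unassigned = dplyr::as_tibble(unassigned))
}

#' RPKM-style normalized unit abundance
#'
#' `abundance = sum(coverage over unit) / (length/1000) / (library_size/1e6)`.
#' `library_size` is an explicit input (e.g. total mapped bases of the
#' library); it is never inferred from the track.
#'
#' @param track A [coverage_track()].
#' @param units Unit tibble (`unit_id`, `chrom`, `start`, `end`).
#' @param library_size Positive library-size normalizer.
#' @return Tibble `unit_id`, `sample_id`, `abundance`.
#' @export
unit_abundance <- function(track, units, library_size) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0) {
    stop("unit_abundance: library_size must be a positive scalar", call. = FALSE)
  }
  if (nrow(units) == 0) {
    return(tibble::tibble(unit_id = character(), sample_id = character(),
                          abundance = numeric()))
  }
  tibble::tibble(
    unit_id = units$unit_id,
    sample_id = track$sample_id,
    abundance = purrr::pmap_dbl(
      units[, c("chrom", "start", "end")],
      function(chrom, start, end) {
        track_sum(track, chrom, start, end) /
          ((end - start) / 1000) / (library_size / 1e6)
      }
    )
  )
}
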