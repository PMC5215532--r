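# Regulatory-element assembly: +/-20 kb colocalization of active marks in
# expressing samples (and repressive marks in silent ones), chromatin-state
# category mapping, and localized acetylation-dip detection at DNase summits.

#' Colocalization configuration
#'
#' @param flank_bp Half-width (bp) of the search window around a unit.
#' @param active_marks Assays whose peaks must base-wise co-occur in an
#'   expressing sample (conjunction).
#' @param repressive_marks Assays accepted as repressive evidence in
#'   non-expressing samples (disjunction: any one suffices).
#' @param min_expressing_support Number of expressing samples in which a base
#'   must pass the active-mark conjunction.
#' @param require_repressive Require each candidate base to also lie in a
#'   repressive-mark peak of at least one non-expressing sample.
#' @param merge_gap Gap (bp) across which merged candidates are re-merged.
#' @return A `coloc_config` list.
#' @export
coloc_config <- function(flank_bp = 20000L,
                         active_marks = c("H3K27ac", "H3K4me3", "DNase"),
                         repressive_marks = c("H3K27me3", "H3K9me3"),
                         min_expressing_support = 1L,
                         require_repressive = TRUE,
                         merge_gap = 200L) {
  stopifnot(flank_bp > 0, length(active_marks) >= 1,
            min_expressing_support >= 1, merge_gap >= 0)
  structure(list(flank_bp = as.integer(flank_bp),
                 active_marks = active_marks,
                 repressive_marks = repressive_marks,
                 min_expressing_support = as.integer(min_expressing_support),
                 require_repressive = isTRUE(require_repressive),
                 merge_gap = as.integer(merge_gap)),
            class = "coloc_config")
}

#' Search window around a transcription unit
#'
#' The window extends `flank_bp` upstream and downstream of the unit,
#' clamped to `[0, chrom_length)`; strand is preserved.
#'
#' @param unit One-row unit tibble (`chrom`, `start`, `end`, `strand`).
#' @param flank_bp Positive flank width (bp); the published procedure used
#'   20 kb on each side.
#' @param chrom_length Chromosome length (bp).
#' @return One-row interval tibble.
#' @export
search_window <- function(unit, flank_bp = 20000L, chrom_length) {
  stopifnot(nrow(unit) == 1, flank_bp > 0, chrom_length >= unit$end)
  if (unit$start < 0 || unit$end > chrom_length) {
    stop("search_window: unit outside chromosome bounds", call. = FALSE)
  }
  tibble::tibble(chrom = unit$chrom,
                 start = max(0L, as.integer(unit$start - flank_bp)),
                 end = min(as.integer(chrom_length), as.integer(unit$end + flank_bp)),
                 strand = unit$strand)
}

#' Colocalize active and repressive peak evidence into candidate elements
#'
#' Within the window, a base is a candidate when the base-wise conjunction of
#' all `active_marks` peaks holds in at least `min_expressing_support`
#' expressing samples; with `require_repressive`, the base must additionally
#' be covered by at least one repressive-mark peak in at least one
#' non-expressing sample. Contiguous candidate bases are merged, then merged
#' again across gaps of at most `merge_gap`.
#'
#' @param window One-row interval tibble from [search_window()].
#' @param peaks Peak tibble: `chrom`, `start`, `end`, `sample_id`, `assay`.
#' @param expressing Character vector of expressing sample ids; remaining
#'   sample ids present in `peaks` are treated as non-expressing.
#' @param cfg A [coloc_config()].
#' @return Interval tibble of candidate elements (possibly empty). An empty
#'   `expressing` set yields an empty result with a warning (the procedure is
#'   undefined without expressing samples).
#' @export
colocalize <- function(window, peaks, expressing, cfg = coloc_config()) {
  stopifnot(inherits(cfg, "coloc_config"), nrow(window) == 1)
  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  if (length(expressing) == 0) {
    warning("colocalize: empty expressing set; returning no candidates", call. = FALSE)
    return(empty)
  }
  validate_intervals(peaks, "colocalize(peaks)")
  win <- window[, c("chrom", "start", "end")]
  pk <- intersect_peaks_window(peaks, win)
  per_sample <- purrr::map(expressing, function(s) {
    sets <- purrr::map(cfg$active_marks, function(a) {
      pk[pk$sample_id == s & pk$assay == a, c("chrom", "start", "end"), drop = FALSE]
    })
    if (any(purrr::map_int(sets, nrow) == 0)) return(empty)
    Reduce(intersect_intervals, sets)
  })
  cand <- .support_intervals(per_sample, cfg$min_expressing_support)
  if (nrow(cand) == 0) return(empty)
  if (cfg$require_repressive) {
    non_expr <- setdiff(unique(pk$sample_id), expressing)
    repr <- pk[pk$sample_id %in% non_expr & pk$assay %in% cfg$repressive_marks,
               c("chrom", "start", "end"), drop = FALSE]
    if (nrow(repr) == 0) return(empty)
    cand <- intersect_intervals(cand, repr)
    if (nrow(cand) == 0) return(empty)
  }
  merge_intervals(cand, max_gap = cfg$merge_gap)
}

# clip peak intervals to a window, keeping sample_id/assay
intersect_peaks_window <- function(peaks, win) {
  p <- peaks[peaks$chrom == win$chrom & peaks$end > win$start & peaks$start < win$end, ,
             drop = FALSE]
  if (nrow(p) == 0) return(p)
  p$start <- pmax(p$start, win$start)
  p$end <- pmin(p$end, win$end)
  p
}

#' Classify a candidate element as promoter or enhancer
#'
#' Rules, applied in order (exactly one category per element):
#' a candidate within `tss_distance_bp` of the unit's strand-aware 5' end
#' that overlaps H3K4me3 is a promoter — `promoter_poised` when some single
#' sample carries both H3K4me3 and H3K27me3 over it (bivalent), else
#' `promoter_active`. A distal candidate with H3K27ac and DNase in the same
#' sample is an enhancer — `genic_enhancer` when inside the unit body,
#' `enhancer_bivalent` when a sample combines enhancer marks with H3K27me3,
#' else `enhancer`. Anything else is `other`. A p300 peak overlap sets the
#' `p300` flag. Distance is nearest-edge, signed negative upstream of the
#' TSS.
#'
#' @param candidate One-row interval tibble.
#' @param unit One-row unit tibble (stranded, with `unit_id`).
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `sample_id`, `assay`).
#' @param states Optional state-segment tibble from [read_state_bed()]
#'   (rows for several samples bound together); per-sample majority-overlap
#'   state labels are recorded.
#' @param tss_distance_bp Promoter distance threshold (bp).
#' @param state_ranking Tie-break order for majority states (most active
#'   first).
#' @return One-row tibble: `chrom`, `start`, `end`, `strand`, `unit_id`,
#'   `category`, `p300`, `distance_to_tss`, plus a `states` list-column of
#'   per-sample labels.
#' @export
classify_element <- function(candidate, unit, peaks, states = NULL,
                             tss_distance_bp = 2000L,
                             state_ranking = c("Active TSS", "Flanking active TSS",
                                               "Enhancer", "Genic Enhancer",
                                               "Bivalent/Poised TSS",
                                               "Bivalent Enhancer")) {
  stopifnot(nrow(candidate) == 1, nrow(unit) == 1, unit$strand %in% c("+", "-"))
  tss <- if (unit$strand == "+") unit$start else unit$end
  dist <- if (candidate$start <= tss && tss < candidate$end) {
    0L
  } else if (candidate$end <= tss) {
    as.integer(candidate$end - 1L - tss)   # candidate left of TSS
  } else {
    as.integer(candidate$start - tss)
  }
  # sign: negative upstream of the 5' end in transcription orientation
  if (unit$strand == "-") dist <- -dist
  ov_assays <- function(sample = NULL) {
    p <- peaks[peaks$chrom == candidate$chrom & peaks$end > candidate$start &
                 peaks$start < candidate$end, , drop = FALSE]
    if (!is.null(sample)) p <- p[p$sample_id == sample, , drop = FALSE]
    unique(p$assay)
  }
  samples_here <- unique(peaks$sample_id)
  has_in_one_sample <- function(assays) {
    any(purrr::map_lgl(samples_here, function(s) all(assays %in% ov_assays(s))))
  }
  all_assays <- ov_assays()
  bivalent_prom <- has_in_one_sample(c("H3K4me3", "H3K27me3"))
  enhancer_marks <- has_in_one_sample(c("H3K27ac", "DNase"))
  bivalent_enh <- has_in_one_sample(c("H3K27ac", "DNase", "H3K27me3"))
  inside_unit <- candidate$chrom == unit$chrom &&
    candidate$start >= unit$start && candidate$end <= unit$end
  category <- if (abs(dist) <= tss_distance_bp && "H3K4me3" %in% all_assays) {
    if (bivalent_prom) "promoter_poised" else "promoter_active"
  } else if (enhancer_marks) {
    if (inside_unit) "genic_enhancer" else if (bivalent_enh) "enhancer_bivalent" else "enhancer"
  } else {
    "other"
  }
  st <- if (!is.null(states) && nrow(states) > 0) {
    sample_ids <- sort(unique(states$sample_id), method = "radix")
    stats::setNames(purrr::map(sample_ids, function(s) {
      majority_state(candidate, states[states$sample_id == s, , drop = FALSE],
                     state_ranking)
    }), sample_ids)
  } else {
    list()
  }
  tibble::tibble(chrom = candidate$chrom, start = candidate$start,
                 end = candidate$end, strand = unit$strand,
                 unit_id = unit$unit_id, category = category,
                 p300 = "p300" %in% all_assays,
                 distance_to_tss = dist, states = list(st))
}

#' Majority-overlap chromatin state of an interval
#'
#' The state segment covering the most bases of the interval wins; ties
#' break toward the earlier entry of `state_ranking` (more active states
#' first), then alphabetically.
#'
#' @param interval One-row interval tibble.
#' @param segments State segments for one sample (`chrom`, `start`, `end`,
#'   `state`).
#' @param state_ranking Character vector, most active state first.
#' @return State label, or `NA_character_` when nothing overlaps.
#' @export
majority_state <- function(interval, segments,
                           state_ranking = character()) {
  s <- segments[segments$chrom == interval$chrom &
                  segments$end > interval$start &
                  segments$start < interval$end, , drop = FALSE]
  if (nrow(s) == 0) return(NA_character_)
  ov <- pmin(s$end, interval$end) - pmax(s$start, interval$start)
  agg <- tapply(ov, s$state, sum)
  best <- names(agg)[agg == max(agg)]
  if (length(best) == 1) return(best)
  rank <- match(best, state_ranking)
  rank[is.na(rank)] <- length(state_ranking) + 1L
  best[order(rank, best)][1]
}

#' Detect a localized dip in binned acetylation signal at an anchor
#'
#' Finds the local minimum of the signal within `max_anchor_distance` of the
#' anchor (a DNase summit), takes the maximum signal within
#' `shoulder_window` on each side of that minimum as the shoulders, and
#' reports a dip iff `min_value <= (1 - min_depth_fraction) * min(shoulders)`.
#'
#' @param signal A [coverage_track()] of binned signal spanning the peak.
#' @param peak One-row interval tibble (the acetylation peak examined).
#' @param anchor Base position inside the peak (typically the DNase summit).
#' @param min_depth_fraction Required fractional depth in (0, 1).
#' @param max_anchor_distance Search radius (bp) around the anchor.
#' @param shoulder_window Shoulder search width (bp) on each side.
#' @return One-row tibble `center`, `depth_fraction`, `shoulder_value`,
#'   `anchor_distance`, or `NULL` when no qualifying dip exists.
#' @export
detect_dip <- function(signal, peak, anchor, min_depth_fraction = 0.3,
                       max_anchor_distance = 250L, shoulder_window = 1000L) {
  stopifnot(inherits(signal, "coverage_track"), nrow(peak) == 1)
  stopifnot(min_depth_fraction > 0, min_depth_fraction < 1)
  if (anchor < peak$start || anchor >= peak$end) {
    stop("detect_dip: anchor outside the examined peak", call. = FALSE)
  }
  bins <- signal$runs[signal$runs$chrom == peak$chrom &
                        signal$runs$end > peak$start &
                        signal$runs$start < peak$end, , drop = FALSE]
  if (nrow(bins) == 0) stop("detect_dip: signal does not span the peak", call. = FALSE)
  mid <- (bins$start + bins$end) / 2
  near <- which(abs(mid - anchor) <= max_anchor_distance)
  if (length(near) == 0) return(NULL)
  vmin <- min(bins$value[near])
  cand <- near[bins$value[near] == vmin]
  center_i <- cand[order(abs(mid[cand] - anchor), mid[cand])][1]
  center <- mid[center_i]
  left <- bins$value[mid < center & mid >= center - shoulder_window]
  right <- bins$value[mid > center & mid <= center + shoulder_window]
  if (length(left) == 0 || length(right) == 0) return(NULL)
  shoulder <- min(max(left), max(right))
  if (shoulder <= 0 || vmin > (1 - min_depth_fraction) * shoulder) return(NULL)
  tibble::tibble(center = center,
                 depth_fraction = 1 - vmin / shoulder,
                 shoulder_value = shoulder,
                 anchor_distance = abs(center - anchor))
}

#' Poised-to-active chromatin-state transition index
#'
#' Returns the earliest 0-based index in `sample_order` where the element's
#' state is in `active_states` after having been in `poised_states` at some
#' earlier index; `NA` otherwise. Samples missing from `states_by_sample`
#' are skipped with a warning.
#'
#' @param states_by_sample Named list (or named character vector) of state
#'   labels per sample.
#' @param sample_order Ordered character vector of sample ids
#'   (differentiation order).
#' @param poised_states,active_states State-label sets.
#' @return Integer 0-based transition index or `NA_integer_`.
#' @export
state_transition <- function(states_by_sample, sample_order,
                             poised_states = c("Bivalent/Poised TSS",
                                               "Bivalent Enhancer"),
                             active_states = c("Active TSS",
                                               "Flanking active TSS",
                                               "Enhancer", "Genic Enhancer")) {
  states_by_sample <- unlist(states_by_sample)
  missing <- setdiff(sample_order, names(states_by_sample))
  if (length(missing) > 0) {
    warning(sprintf("state_transition: samples without states skipped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  kept <- sample_order[sample_order %in% names(states_by_sample)]
  s <- states_by_sample[kept]
  seen_poised <- FALSE
  for (i in seq_along(s)) {
    if (seen_poised && s[i] %in% active_states) {
      return(match(kept[i], sample_order) - 1L)
    }
    if (s[i] %in% poised_states) seen_poised <- TRUE
  }
  NA_integer_
}
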