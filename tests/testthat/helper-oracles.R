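# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no Biostrings matching, no IRanges algebra): plain string
# search, per-base logical masks, and linear scans.

# -- degenerate motifs --------------------------------------------------------

# tiny bracket parser (brackets + plain ACGT only; enough for the FOX motif)
oracle_expand_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      grp <- character()
      while (chars[j] != "]") {
        grp <- c(grp, chars[j])
        j <- j + 1L
      }
      sets[[length(sets) + 1L]] <- grp
      i <- j + 1L
    } else {
      sets[[length(sets) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  unique(apply(grid, 1, paste, collapse = ""))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# all 0-based offsets of fixed word `w` in `seq` (overlapping occurrences)
oracle_word_offsets <- function(seq, w) {
  m <- gregexpr(paste0("(?=", w, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# expand the motif into concrete words and string-search each on both strands
oracle_iupac_hits <- function(seq, pattern) {
  words <- oracle_expand_motif(pattern)
  k <- nchar(words[1])
  plus <- sort(unique(unlist(lapply(words, function(w) oracle_word_offsets(seq, w)))))
  minus <- sort(unique(unlist(lapply(words, function(w) {
    oracle_word_offsets(seq, oracle_revcomp(w))
  }))))
  rbind(
    if (length(plus)) data.frame(start = plus, end = plus + k, strand = "+"),
    if (length(minus)) data.frame(start = minus, end = minus + k, strand = "-")
  )
}

# -- unit calling -------------------------------------------------------------

# logical-vector runs -> 0-based [start, end) intervals
oracle_runs_from_mask <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# threshold -> run-length -> gap-merge -> length filter, on a per-base vector
oracle_call_units <- function(values, min_cov, max_gap, min_len) {
  runs <- oracle_runs_from_mask(values >= min_cov)
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] <= max_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged[merged$end - merged$start >= min_len, , drop = FALSE]
}

# -- colocalization -----------------------------------------------------------

# per-base boolean-mask evaluation of the colocalization rule
oracle_colocalize <- function(win, peaks, expressing, active_marks,
                              repressive_marks, min_support,
                              require_repressive, merge_gap) {
  n <- win$end - win$start
  mask_of <- function(sub) {
    m <- logical(n)
    for (i in seq_len(nrow(sub))) {
      a <- max(sub$start[i], win$start) - win$start + 1L
      b <- min(sub$end[i], win$end) - win$start
      if (b >= a) m[a:b] <- TRUE
    }
    m
  }
  support <- integer(n)
  for (s in expressing) {
    ok <- rep(TRUE, n)
    for (a in active_marks) {
      ok <- ok & mask_of(peaks[peaks$sample_id == s & peaks$assay == a &
                                 peaks$chrom == win$chrom, , drop = FALSE])
    }
    support <- support + ok
  }
  cand <- support >= min_support
  if (require_repressive) {
    non_expr <- setdiff(unique(peaks$sample_id), expressing)
    cand <- cand & mask_of(peaks[peaks$sample_id %in% non_expr &
                                   peaks$assay %in% repressive_marks &
                                   peaks$chrom == win$chrom, , drop = FALSE])
  }
  runs <- oracle_runs_from_mask(cand)
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged$start <- merged$start + win$start
  merged$end <- merged$end + win$start
  merged
}

# -- helpers to build random fixtures ----------------------------------------

# random per-base coverage vector plus the equivalent coverage_track
random_track_fixture <- function(len = 3000, strand = "+", sample_id = "s1",
                                 lambda = 1.2, zero_frac = 0.5) {
  values <- stats::rpois(len, lambda) * (stats::runif(len) > zero_frac)
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values > 0
  runs <- tibble::tibble(chrom = "chrT", start = as.integer(starts[keep]),
                         end = as.integer(ends[keep]), value = r$values[keep])
  list(values = as.numeric(values),
       track = coverage_track(runs, sample_id = sample_id, strand = strand))
}

random_peaks_fixture <- function(win, samples, assays, n_per = 3, min_w = 50,
                                 max_w = 400) {
  rows <- list()
  for (s in samples) {
    for (a in assays) {
      k <- sample(0:n_per, 1)
      if (k == 0) next
      st <- sort(sample(seq(win$start, win$end - max_w), k))
      w <- sample(min_w:max_w, k, replace = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = win$chrom, start = st, end = pmin(st + w, win$end),
        sample_id = s, assay = a
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), sample_id = character(),
                          assay = character())
  }
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

FOX_PATTERN <- "[AC]A[AT]T[AG]TT[GT][AG][CT]T[CT]"
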