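# Degenerate-motif and PWM scanning with conservation gating.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.set_to_iupac <- local({
  codes <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  function(set) names(codes)[match(paste(sort(unique(set)), collapse = ""), codes)]
})

#' Parse a bracket/IUPAC degenerate motif
#'
#' Accepts bracket groups (`[AC]`) and single IUPAC ambiguity letters
#' (`R Y S W K M B D H V N`); each position becomes an allowed-base set.
#'
#' @param pattern Motif text, e.g. the forkhead-box consensus
#'   `"[AC]A[AT]T[AG]TT[GT][AG][CT]T[CT]"`.
#' @param label Motif name.
#' @return An `iupac_motif`: list with `label`, `sets` (list of allowed-base
#'   sets), `iupac` (equivalent IUPAC string), `length` and `degeneracy`
#'   (product of set sizes).
#' @examples
#' m <- parse_iupac("[AC]A[AT]T[AG]TT[GT][AG][CT]T[CT]", "FOX")
#' m$degeneracy # 128
#' @export
parse_iupac <- function(pattern, label = "motif") {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  chars <- strsplit(toupper(pattern), "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0) stop("parse_iupac: unbalanced bracket", call. = FALSE)
      close <- close[1]
      grp <- chars[(i + 1L):(close - 1L)]
      if (length(grp) == 0 || !all(grp %in% c("A", "C", "G", "T"))) {
        stop(sprintf("parse_iupac: bracket group must contain only A/C/G/T, got [%s]",
                     paste(grp, collapse = "")), call. = FALSE)
      }
      sets <- c(sets, list(unique(grp)))
      i <- close + 1L
    } else if (ch == "]") {
      stop("parse_iupac: unbalanced bracket", call. = FALSE)
    } else if (ch %in% names(.IUPAC_SETS)) {
      sets <- c(sets, list(.IUPAC_SETS[[ch]]))
      i <- i + 1L
    } else {
      stop(sprintf("parse_iupac: '%s' is not a DNA base or IUPAC code", ch),
           call. = FALSE)
    }
  }
  structure(list(label = label, sets = sets,
                 iupac = paste(vapply(sets, .set_to_iupac, ""), collapse = ""),
                 length = length(sets),
                 degeneracy = prod(lengths(sets))),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("<iupac_motif> %s: %s (length %d, degeneracy %d)\n",
              x$label, x$iupac, x$length, x$degeneracy))
  invisible(x)
}

.as_dnastring <- function(sequence) {
  if (inherits(sequence, "DNAString")) sequence
  else Biostrings::DNAString(toupper(as.character(sequence)))
}

.hit_tbl <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), motif_label = character(), score = numeric())
}

#' Scan a sequence for exact degenerate-motif matches
#'
#' Every offset where each base is a member of the positional allowed set is
#' a hit (no mismatches); `N` in the sequence never matches. Minus-strand
#' hits are found on the reverse complement and mapped back to plus-strand
#' coordinates. Overlapping hits are all reported.
#'
#' @param sequence Character or `DNAString` over `{A,C,G,T,N}`.
#' @param motif An [parse_iupac()] motif.
#' @param both_strands Scan the reverse complement too.
#' @param chrom Chromosome label attached to hits.
#' @param offset 0-based genomic offset of the first sequence base.
#' @return Hit tibble `chrom`, `start`, `end`, `strand`, `motif_label`,
#'   `score` (1 for exact degenerate matches), sorted by (start, strand).
#' @export
scan_iupac <- function(sequence, motif, both_strands = TRUE,
                       chrom = "seq", offset = 0L) {
  stopifnot(inherits(motif, "iupac_motif"))
  s <- .as_dnastring(sequence)
  L <- length(s)
  if (L < motif$length) return(.hit_tbl())
  one <- function(subject, strand) {
    # fixed="subject": IUPAC codes in the pattern are degenerate, but
    # subject letters are literal, so N in the sequence never matches
    m <- Biostrings::matchPattern(motif$iupac, subject, fixed = "subject")
    if (length(m) == 0) return(NULL)
    st <- Biostrings::start(m) - 1L
    if (strand == "-") st <- L - (st + motif$length)
    tibble::tibble(chrom = chrom, start = as.integer(offset + st),
                   end = as.integer(offset + st + motif$length),
                   strand = strand, motif_label = motif$label, score = 1)
  }
  hits <- list(one(s, "+"))
  if (both_strands) hits <- c(hits, list(one(Biostrings::reverseComplement(s), "-")))
  out <- dplyr::bind_rows(purrr::compact(hits))
  if (nrow(out) == 0) return(.hit_tbl())
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Build a log2-odds PWM from a count or probability matrix
#'
#' @param counts 4-row matrix (rows A, C, G, T; columns = positions) of
#'   counts or probabilities.
#' @param background Base frequencies (A, C, G, T), strictly positive,
#'   summing to 1.
#' @param pseudocount Added to each count before normalization.
#' @param label Motif name.
#' @return A `pwm` object holding the log2-odds `matrix` (bits).
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4),
                            pseudocount = 0.01, label = "pwm") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, all(counts >= 0), all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  rownames(counts) <- c("A", "C", "G", "T")
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log2(sweep(p, 1, background, "/"))
  structure(list(matrix = lo, background = background, label = label,
                 length = ncol(lo)),
            class = "pwm")
}

#' Scan a sequence with a log2-odds PWM
#'
#' Per-window score is the sum over positions of `log2(p(base)/background)`
#' read from the stored log-odds matrix; windows scoring at or above the
#' threshold are reported. Windows containing `N` are skipped.
#'
#' @param sequence Character or `DNAString`.
#' @param pwm A [pwm_from_counts()] object.
#' @param score_threshold Minimum reported score (bits); finite.
#' @param both_strands Scan the reverse complement too.
#' @param chrom,offset Coordinates attached to hits (as in [scan_iupac()]).
#' @return Hit tibble with `score` in bits, sorted by (start, strand).
#' @export
scan_pwm <- function(sequence, pwm, score_threshold, both_strands = TRUE,
                     chrom = "seq", offset = 0L) {
  stopifnot(inherits(pwm, "pwm"), is.finite(score_threshold))
  s <- .as_dnastring(sequence)
  L <- length(s)
  k <- pwm$length
  if (L < k) return(.hit_tbl())
  score_strand <- function(subject, strand) {
    idx <- match(strsplit(as.character(subject), "")[[1]], c("A", "C", "G", "T"))
    n_win <- L - k + 1L
    sc <- numeric(n_win)
    ok <- rep(TRUE, n_win)
    for (j in seq_len(k)) {
      b <- idx[j:(n_win + j - 1L)]
      ok <- ok & !is.na(b)
      v <- pwm$matrix[cbind(ifelse(is.na(b), 1L, b), j)]
      sc <- sc + v
    }
    keep <- which(ok & sc >= score_threshold)
    if (length(keep) == 0) return(NULL)
    st <- keep - 1L
    if (strand == "-") st <- L - (st + k)
    tibble::tibble(chrom = chrom, start = as.integer(offset + st),
                   end = as.integer(offset + st + k), strand = strand,
                   motif_label = pwm$label, score = sc[keep])
  }
  hits <- list(score_strand(s, "+"))
  if (both_strands) {
    hits <- c(hits, list(score_strand(Biostrings::reverseComplement(s), "-")))
  }
  out <- dplyr::bind_rows(purrr::compact(hits))
  if (nrow(out) == 0) return(.hit_tbl())
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Filter motif hits by mean per-base conservation
#'
#' Keeps hits whose mean conservation over the hit interval reaches
#' `min_mean` (the published gate was > 0.8 phastCons); uncovered bases
#' contribute 0. Retained hits carry `mean_conservation`. The filter is
#' idempotent and monotone in `min_mean`.
#'
#' @param hits Hit tibble from [scan_iupac()]/[scan_pwm()].
#' @param conservation A [coverage_track()] of per-base scores in `[0, 1]`.
#' @param min_mean Minimum mean conservation in `[0, 1]`.
#' @return Filtered hit tibble with a `mean_conservation` column.
#' @export
conservation_filter <- function(hits, conservation, min_mean = 0.8) {
  stopifnot(inherits(conservation, "coverage_track"),
            min_mean >= 0, min_mean <= 1)
  if (nrow(conservation$runs) > 0 &&
      (any(conservation$runs$value > 1) || any(conservation$runs$value < 0))) {
    stop("conservation_filter: conservation values must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(hits) == 0) {
    return(dplyr::mutate(hits, mean_conservation = numeric(0)))
  }
  hits$mean_conservation <- purrr::pmap_dbl(
    hits[, c("chrom", "start", "end")],
    function(chrom, start, end) track_mean(conservation, chrom, start, end)
  )
  dplyr::filter(hits, .data$mean_conservation >= min_mean)
}

#' Read motifs from a text file
#'
#' Two layouts are accepted: tab-separated `label<TAB>pattern` lines
#' (degenerate motifs), or JASPAR-style blocks (`>label` followed by four
#' `A|C|G|T [counts...]` rows) which become PWMs.
#'
#' @param path Motif file.
#' @param background,pseudocount Passed to [pwm_from_counts()] for matrix
#'   blocks.
#' @return Named list of `iupac_motif`/`pwm` objects.
#' @export
read_motifs <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      label <- trimws(sub("^>", "", ln))
      rows <- lines[(i + 1L):(i + 4L)]
      counts <- t(vapply(rows, function(r) {
        nums <- gsub("^[ACGT]\\s*|\\[|\\]", "", r)
        as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
      }, numeric(length(strsplit(trimws(gsub("^[ACGT]\\s*|\\[|\\]", "", rows[1])),
                                 "\\s+")[[1]]))))
      out[[label]] <- pwm_from_counts(counts, background, pseudocount, label)
      i <- i + 5L
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop(sprintf("%s: expected 'label<TAB>pattern' at '%s'", path, ln),
             call. = FALSE)
      }
      out[[parts[1]]] <- parse_iupac(parts[2], parts[1])
      i <- i + 1L
    }
  }
  out
}

#' Write motif hits as BED6
#'
#' Score column carries bits times 100, integer-rounded.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$chrom, hits$start, hits$end,
                   hits$motif_label, as.integer(round(hits$score * 100)),
                   hits$strand)
  writeLines(lines, path)
  invisible(path)
}
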