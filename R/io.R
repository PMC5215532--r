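# Text-format readers/writers. All hand-parsed line by line so that malformed
# records are rejected with the offending line number rather than silently
# repaired; coordinates stay 0-based half-open internally.

.read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.parse_int <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | x != as.character(v))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-integer %s at line %d ('%s')", path, what,
                 lineno[bad[1]], x[bad[1]]), call. = FALSE)
  }
  v
}

#' Read a BED3/BED6 file
#'
#' Lines starting with `track`, `browser` or `#` are skipped. Columns 4 and 6
#' populate `name` and `strand` when present.
#'
#' @param path Path to a BED file.
#' @param default_strand Strand used when the file has no column 6.
#' @return Interval tibble (`chrom`, `start`, `end`, `strand`, `name`).
#' @export
read_bed <- function(path, default_strand = ".") {
  stopifnot(default_strand %in% c("+", "-", "."))
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(gi(character(), integer(), integer()))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("%s: fewer than 3 fields at line %d", path,
                 dat$lineno[which(nf < 3)[1]]), call. = FALSE)
  }
  f <- function(i) vapply(fields, function(x) if (length(x) >= i) x[i] else NA_character_, "")
  start <- .parse_int(f(2), dat$lineno, path, "start")
  end <- .parse_int(f(3), dat$lineno, path, "end")
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid interval (start >= end or negative) at line %d",
                 path, dat$lineno[bad[1]]), call. = FALSE)
  }
  name <- f(4)
  strand <- f(6)
  strand[is.na(strand) | !(strand %in% c("+", "-", "."))] <- default_strand
  gi(f(1), start, end, strand, name)
}

#' Read a 4-column bedGraph into a coverage track
#'
#' Runs are sorted, validated (no overlap between input lines, values finite
#' and >= 0) and bookended equal-valued runs are coalesced.
#'
#' @param path Path to a bedGraph file.
#' @param sample_id Sample label attached to the track.
#' @param strand Strand tag for the track (bedGraph has no strand column).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sample_id = "sample", strand = ".") {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(coverage_track(tibble::tibble(chrom = character(), start = integer(),
                                         end = integer(), value = numeric()),
                          sample_id, strand))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop(sprintf("%s: fewer than 4 fields at line %d", path,
                 dat$lineno[which(nf < 4)[1]]), call. = FALSE)
  }
  f <- function(i) vapply(fields, `[`, "", i)
  start <- .parse_int(f(2), dat$lineno, path, "start")
  end <- .parse_int(f(3), dat$lineno, path, "end")
  value <- suppressWarnings(as.numeric(f(4)))
  if (anyNA(value)) {
    stop(sprintf("%s: non-numeric value at line %d", path,
                 dat$lineno[which(is.na(value))[1]]), call. = FALSE)
  }
  if (any(value < 0)) {
    stop(sprintf("%s: negative value at line %d", path,
                 dat$lineno[which(value < 0)[1]]), call. = FALSE)
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid interval at line %d", path, dat$lineno[bad[1]]),
         call. = FALSE)
  }
  runs <- tibble::tibble(chrom = f(1), start = start, end = end, value = value)
  tryCatch(
    coverage_track(runs, sample_id, strand),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  )
}

#' Read a chromatin-state BED (label in column 4)
#'
#' State labels are validated against a vocabulary; unknown labels are kept
#' but mapped to category `"other"` with a warning. Overlapping segments for
#' one sample violate the tiling invariant and raise an error.
#'
#' @param path Path to a BED file whose name column holds the state label.
#' @param sample_id Sample label.
#' @param vocabulary Character vector of known state labels.
#' @return Tibble with `chrom`, `start`, `end`, `sample_id`, `state`
#'   (vocabulary label or `"other"`) and `state_raw` (label as written).
#' @export
read_state_bed <- function(path, sample_id, vocabulary) {
  x <- read_bed(path)
  if (nrow(x) > 0 && all(is.na(x$name))) {
    stop(sprintf("%s: state BED requires a name column", path), call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  ov <- x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(prev_end = dplyr::lag(.data$end, default = -1L)) |>
    dplyr::ungroup()
  if (any(ov$start < ov$prev_end)) {
    bad <- which(ov$start < ov$prev_end)[1]
    stop(sprintf("%s: overlapping state segments at %s:%d (sample %s)", path,
                 x$chrom[bad], x$start[bad], sample_id), call. = FALSE)
  }
  state <- ifelse(x$name %in% vocabulary, x$name, "other")
  unknown <- unique(x$name[state == "other"])
  if (length(unknown) > 0) {
    warning(sprintf("%s: state labels outside vocabulary mapped to 'other': %s",
                    path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                 sample_id = sample_id, state = state, state_raw = x$name)
}

#' Write intervals (units, elements, hits) as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' closed convention; every extra column becomes a `key=value` attribute so
#' a read-back with [read_gff3()] reproduces coordinates exactly.
#'
#' @param x Interval tibble; extra columns become attributes. A `type` column,
#'   if present, fills GFF3 column 3 (default `"region"`).
#' @param path Output path.
#' @param source Value for GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path, source = "pritx") {
  validate_intervals(x, "write_gff3")
  header <- "##gff-version 3"
  if (nrow(x) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  type <- if ("type" %in% names(x)) as.character(x$type) else rep("region", nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) format(x$score, trim = TRUE) else rep(".", nrow(x))
  attr_cols <- setdiff(names(x), c("chrom", "start", "end", "strand", "type", "score"))
  esc <- function(v) {
    v <- as.character(v)
    v <- gsub("%", "%25", v, fixed = TRUE)
    v <- gsub(";", "%3B", v, fixed = TRUE)
    v <- gsub("=", "%3D", v, fixed = TRUE)
    gsub(",", "%2C", v, fixed = TRUE)
  }
  attrs <- vapply(seq_len(nrow(x)), function(i) {
    kv <- purrr::compact(purrr::map(attr_cols, function(col) {
      v <- x[[col]][i]
      if (is.na(v)) return(NULL)
      if (is.numeric(v)) v <- format(v, trim = TRUE, digits = 12) else v <- esc(v)
      sprintf("%s=%s", col, v)
    }))
    if (length(kv) == 0) "." else paste(unlist(kv), collapse = ";")
  }, "")
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   x$chrom, source, type, x$start + 1L, x$end, score, strand, attrs)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read back a GFF3 file written by [write_gff3()]
#'
#' @param path Path to a GFF3 file.
#' @return Interval tibble with 0-based half-open coordinates, `type`,
#'   `strand`, and one column per attribute key (character).
#' @export
read_gff3 <- function(path) {
  dat <- .read_data_lines(path)
  if (length(dat$lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          strand = character(), type = character()))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9)) {
    stop(sprintf("%s: GFF3 line without 9 fields at line %d", path,
                 dat$lineno[which(lengths(fields) != 9)[1]]), call. = FALSE)
  }
  f <- function(i) vapply(fields, `[`, "", i)
  unesc <- function(v) {
    v <- gsub("%2C", ",", v, fixed = TRUE)
    v <- gsub("%3D", "=", v, fixed = TRUE)
    v <- gsub("%3B", ";", v, fixed = TRUE)
    gsub("%25", "%", v, fixed = TRUE)
  }
  base <- tibble::tibble(
    chrom = f(1),
    start = .parse_int(f(4), dat$lineno, path, "start") - 1L,
    end = .parse_int(f(5), dat$lineno, path, "end"),
    strand = f(7),
    type = f(3)
  )
  attr_tbls <- purrr::map(f(9), function(a) {
    if (a == ".") return(tibble::tibble(.rows = 1))
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- purrr::map_chr(kv, ~ unesc(.x[2]))
    names(vals) <- purrr::map_chr(kv, 1)
    tibble::as_tibble_row(as.list(vals))
  })
  dplyr::bind_cols(base, dplyr::bind_rows(attr_tbls))
}

#' Read a gene-by-sample expression table
#'
#' Expects a TSV with the gene label in the first column and one column per
#' sample. Values must be finite and >= 0; gene and sample labels unique.
#'
#' @param path Path to the TSV.
#' @return Tibble with column `gene` plus one numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  if (anyDuplicated(x$gene)) stop(sprintf("%s: duplicate gene labels", path), call. = FALSE)
  if (anyDuplicated(names(x))) stop(sprintf("%s: duplicate sample labels", path), call. = FALSE)
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop(sprintf("%s: expression values must be finite and >= 0", path), call. = FALSE)
  }
  dplyr::as_tibble(x)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequence names are
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
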