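test_that("degenerate motif parsing expands brackets and IUPAC codes", {
  m <- parse_iupac(FOX_PATTERN, "FOX")
  expect_equal(m$length, 12L)
  expect_equal(lengths(m$sets), c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 2L, 2L, 1L, 2L))
  expect_equal(m$degeneracy, 128)

  simple <- parse_iupac("ACGT")
  expect_equal(simple$length, 4L)
  expect_equal(simple$degeneracy, 1)
  iupac <- parse_iupac("RYN")
  expect_equal(iupac$sets[[1]], c("A", "G"))
  expect_equal(iupac$sets[[3]], c("A", "C", "G", "T"))

  expect_error(parse_iupac("[AZ]T"), "only A/C/G/T")
  expect_error(parse_iupac("AZT"), "not a DNA base")
  expect_error(parse_iupac("[AC"), "unbalanced")
  expect_error(parse_iupac("A]C"), "unbalanced")
})

test_that("scan_iupac finds forward and reverse-complement hits", {
  fox <- parse_iupac(FOX_PATTERN, "FOX")
  hits <- scan_iupac("AAATATTGACTC", fox)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$start, hits$end, hits$strand), c("0", "12", "+"))
  rc <- scan_iupac("GAGTCAATATTT", fox)
  expect_equal(nrow(rc), 1)
  expect_equal(c(rc$start, rc$end, rc$strand), c("0", "12", "-"))
  expect_equal(nrow(scan_iupac("AAAAAAAAAAAA", fox)), 0)
  # N never matches
  expect_equal(nrow(scan_iupac("AAATATTGNCTC", fox)), 0)
})

test_that("scan_iupac equals the word-expansion string-search oracle", {
  withr::local_seed(1234)
  words <- oracle_expand_motif(FOX_PATTERN)
  expect_equal(length(words), 128)
  expect_equal(length(unique(nchar(words))), 1)
  fox <- parse_iupac(FOX_PATTERN, "FOX")
  for (i in 1:25) {
    seq <- random_dna(10000)
    # plant a couple of instances so hits are guaranteed
    for (w in sample(words, 2)) {
      pos <- sample(1:9000, 1)
      substr(seq, pos, pos + 11) <- w
    }
    got <- scan_iupac(seq, fox)
    want <- oracle_iupac_hits(seq, FOX_PATTERN)
    want <- want[order(want$start, want$strand), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("strand symmetry: hits mirror under reverse complement", {
  withr::local_seed(55)
  fox <- parse_iupac(FOX_PATTERN, "FOX")
  for (i in 1:10) {
    seq <- random_dna(3000)
    w <- oracle_expand_motif(FOX_PATTERN)[sample(128, 1)]
    pos <- sample(1:2900, 1)
    substr(seq, pos, pos + 11) <- w
    fwd <- scan_iupac(seq, fox)
    rev <- scan_iupac(oracle_revcomp(seq), fox)
    n <- nchar(seq)
    mirrored <- tibble::tibble(start = n - rev$end, strand = ifelse(rev$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$strand, mirrored$strand)
  }
})

test_that("PWM scoring matches closed forms and a brute-force window oracle", {
  # matrix equal to background -> every window scores 0
  flat <- pwm_from_counts(matrix(1, 4, 3), pseudocount = 0)
  hits <- scan_pwm("ACGTACGT", flat, score_threshold = -1, both_strands = FALSE)
  expect_equal(nrow(hits), 6)
  expect_true(all(hits$score == 0))

  # one-hot consensus ACG: 3 * log2(4) = 6 bits
  onehot <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  onehot[cbind(c(1, 2, 3), 1:3)] <- 1
  pw <- pwm_from_counts(onehot, pseudocount = 0)
  top <- scan_pwm("ACG", pw, score_threshold = 0)
  expect_equal(top$score[top$strand == "+"], 6)

  withr::local_seed(808)
  counts <- matrix(stats::rpois(4 * 8, 10) + 1, 4, 8)
  pw2 <- pwm_from_counts(counts)
  seq <- random_dna(10000)
  thr <- 4
  got <- scan_pwm(seq, pw2, thr, both_strands = TRUE)
  # brute-force per-window summation oracle
  sc_strand <- function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- match(ch, c("A", "C", "G", "T"))
    vapply(1:(length(ch) - 7), function(o) {
      sum(pw2$matrix[cbind(idx[o:(o + 7)], 1:8)])
    }, numeric(1))
  }
  sp <- sc_strand(seq)
  sm <- sc_strand(oracle_revcomp(seq))
  n <- nchar(seq)
  want_plus <- which(sp >= thr) - 1L
  want_minus <- sort(n - (which(sm >= thr) - 1L) - 8L)
  expect_equal(got$start[got$strand == "+"], want_plus)
  expect_equal(sort(got$start[got$strand == "-"]), want_minus)
  expect_equal(sort(got$score), sort(c(sp[sp >= thr], sm[sm >= thr])))
  # threshold -Inf-ish: every window on each strand
  all_hits <- scan_pwm(seq, pw2, -1e9)
  expect_equal(nrow(all_hits), 2 * (n - 8 + 1))
})

test_that("conservation filter keeps only hits above the mean threshold", {
  cons <- coverage_track(tibble::tibble(chrom = "seq", start = c(0L, 50L),
                                        end = c(50L, 100L), value = c(1, 0.5)),
                         "phastCons")
  hits <- tibble::tibble(chrom = "seq", start = c(10L, 60L), end = c(22L, 72L),
                         strand = "+", motif_label = "m", score = 1)
  kept <- conservation_filter(hits, cons, min_mean = 0.8)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 10L)
  expect_equal(kept$mean_conservation, 1)
  # idempotent and monotone in min_mean
  expect_equal(nrow(conservation_filter(kept, cons, 0.8)), 1)
  expect_equal(nrow(conservation_filter(hits, cons, 0.9)), 1)
  expect_equal(nrow(conservation_filter(hits, cons, 0.4)), 2)

  # piecewise track means equal base-wise averaging
  withr::local_seed(21)
  runs <- tibble::tibble(chrom = "seq", start = seq(0L, 900L, by = 100L),
                         end = seq(100L, 1000L, by = 100L),
                         value = round(stats::runif(10), 2))
  tr <- coverage_track(runs, "c")
  arr <- rep(runs$value, each = 100)
  h <- tibble::tibble(chrom = "seq", start = sample(0:950, 20), strand = "+",
                      motif_label = "m", score = 1)
  h$end <- h$start + 30L
  out <- conservation_filter(h, tr, min_mean = 0)
  expect_equal(out$mean_conservation,
               vapply(seq_len(20), function(i) mean(arr[(h$start[i] + 1):h$end[i]]),
                      numeric(1)))
  expect_error(conservation_filter(h, coverage_track(
    tibble::tibble(chrom = "seq", start = 0L, end = 10L, value = 2), "c")),
    "\\[0, 1\\]")
})

test_that("motif files parse both tab patterns and JASPAR-style blocks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("FOX\t[AC]A[AT]T[AG]TT[GT][AG][CT]T[CT]",
               ">TEST1",
               "A 10 0 2",
               "C 0 12 3",
               "G 1 0 5",
               "T 2 1 3"), f)
  ms <- read_motifs(f)
  expect_s3_class(ms$FOX, "iupac_motif")
  expect_equal(ms$FOX$degeneracy, 128)
  expect_s3_class(ms$TEST1, "pwm")
  expect_equal(ms$TEST1$length, 3L)
})
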