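unit1 <- tibble::tibble(unit_id = "TU01", chrom = "chrT", start = 30000L,
                        end = 50000L, strand = "+")

pk <- function(start, end, sample, assay) {
  tibble::tibble(chrom = "chrT", start = as.integer(start), end = as.integer(end),
                 sample_id = sample, assay = assay)
}

test_that("search window applies the 20 kb flank with clamping", {
  w <- search_window(unit1, 20000, 1e6)
  expect_equal(c(w$start, w$end), c(10000L, 70000L))
  expect_equal(w$strand, "+")
  u2 <- tibble::tibble(unit_id = "u", chrom = "chrT", start = 5000L, end = 8000L,
                       strand = "+")
  expect_equal(search_window(u2, 20000, 1e6)$start, 0L)
  expect_equal(search_window(u2, 20000, 25000)$end, 25000L)
})

test_that("colocalize requires the full active-mark conjunction", {
  win <- tibble::tibble(chrom = "chrT", start = 0L, end = 1000L, strand = "+")
  peaks <- dplyr::bind_rows(pk(100, 300, "s1", "H3K27ac"),
                            pk(150, 400, "s1", "H3K4me3"),
                            pk(180, 260, "s1", "DNase"),
                            pk(100, 400, "s0", "H3K27me3"))
  cfg <- coloc_config()
  got <- colocalize(win, peaks, expressing = "s1", cfg)
  expect_equal(c(got$start, got$end), c(180L, 260L))
  # required mark missing -> nothing
  no_dnase <- peaks[peaks$assay != "DNase", ]
  expect_equal(nrow(colocalize(win, no_dnase, "s1", cfg)), 0)
  # repressive evidence required and absent -> nothing
  no_repr <- peaks[peaks$assay != "H3K27me3", ]
  expect_equal(nrow(colocalize(win, no_repr, "s1", cfg)), 0)
  expect_equal(nrow(colocalize(win, peaks, "s1",
                               coloc_config(require_repressive = FALSE))), 1)
  expect_warning(out <- colocalize(win, peaks, character(0), cfg), "expressing")
  expect_equal(nrow(out), 0)
})

test_that("colocalize equals the per-base boolean-mask oracle and is monotone", {
  withr::local_seed(7117)
  cfg_marks <- c("H3K27ac", "H3K4me3", "DNase")
  repr <- c("H3K27me3", "H3K9me3")
  for (i in 1:30) {
    win <- tibble::tibble(chrom = "chrT", start = 0L, end = 4000L, strand = "+")
    samples <- c("e1", "e2", "n1")
    expressing <- c("e1", "e2")
    peaks <- random_peaks_fixture(win, samples, c(cfg_marks, repr), n_per = 3)
    sup <- sample(1:2, 1)
    rq <- sample(c(TRUE, FALSE), 1)
    mg <- sample(c(0L, 50L, 150L), 1)
    cfg <- coloc_config(min_expressing_support = sup, require_repressive = rq,
                        merge_gap = mg)
    got <- colocalize(win, peaks, expressing, cfg)
    want <- oracle_colocalize(win, peaks, expressing, cfg_marks, repr, sup, rq, mg)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
    }
    # monotone: adding an active peak to an expressing sample never shrinks
    extra <- dplyr::bind_rows(peaks, pk(1000, 1400, "e1",
                                        sample(cfg_marks, 1)))
    grown <- colocalize(win, extra, expressing, cfg)
    expect_gte(sum(grown$end - grown$start), sum(got$end - got$start) -
                 # merging across a new bridge can only add bases
                 0)
    base_cov <- sum(got$end - got$start)
    # raising support never adds candidate bases
    stricter <- colocalize(win, peaks, expressing,
                           coloc_config(min_expressing_support = sup + 1L,
                                        require_repressive = rq, merge_gap = mg))
    expect_lte(sum(stricter$end - stricter$start), base_cov)
  }
})

test_that("element categories follow the promoter/enhancer mark rules", {
  peaks_prom <- dplyr::bind_rows(pk(30200, 30700, "late", "H3K4me3"),
                                 pk(30250, 30650, "late", "DNase"))
  el <- classify_element(gi("chrT", 30300, 30600), unit1, peaks_prom)
  expect_equal(el$category, "promoter_active")
  expect_equal(el$distance_to_tss, 300L)

  # bivalent: H3K4me3 and H3K27me3 in the same sample
  peaks_biv <- dplyr::bind_rows(peaks_prom, pk(30200, 30700, "ESC", "H3K4me3"),
                                pk(30100, 30800, "ESC", "H3K27me3"))
  expect_equal(classify_element(gi("chrT", 30300, 30600), unit1,
                                peaks_biv)$category, "promoter_poised")
  # repressive mark in a different sample does not make it poised
  peaks_split <- dplyr::bind_rows(peaks_prom, pk(30100, 30800, "ESC", "H3K27me3"))
  expect_equal(classify_element(gi("chrT", 30300, 30600), unit1,
                                peaks_split)$category, "promoter_active")

  # distal H3K27ac + DNase + p300 -> enhancer with the p300 flag
  peaks_enh <- dplyr::bind_rows(pk(19500, 20500, "late", "H3K27ac"),
                                pk(19800, 20200, "late", "DNase"),
                                pk(19850, 20150, "late", "p300"))
  enh <- classify_element(gi("chrT", 19800, 20200), unit1, peaks_enh)
  expect_equal(enh$category, "enhancer")
  expect_true(enh$p300)
  expect_equal(enh$distance_to_tss, -9801L)

  # inside the unit body -> genic enhancer
  peaks_gen <- dplyr::bind_rows(pk(39500, 40500, "late", "H3K27ac"),
                                pk(39800, 40200, "late", "DNase"))
  expect_equal(classify_element(gi("chrT", 39800, 40200), unit1,
                                peaks_gen)$category, "genic_enhancer")
  # enhancer marks plus same-sample H3K27me3 -> bivalent enhancer
  peaks_benh <- dplyr::bind_rows(peaks_enh, pk(19700, 20300, "late", "H3K27me3"))
  expect_equal(classify_element(gi("chrT", 19800, 20200), unit1,
                                peaks_benh)$category, "enhancer_bivalent")
  # nothing qualifying -> other
  expect_equal(classify_element(gi("chrT", 19800, 20200), unit1,
                                pk(19800, 20200, "late", "H3K9me3"))$category,
               "other")
})

test_that("majority-overlap state resolution breaks ties toward active", {
  segs <- tibble::tibble(chrom = "chrT", start = c(0L, 100L, 400L),
                         end = c(100L, 400L, 600L),
                         state = c("Quies", "Bivalent/Poised TSS", "Active TSS"))
  expect_equal(majority_state(gi("chrT", 150, 500), segs), "Bivalent/Poised TSS")
  expect_equal(majority_state(gi("chrT", 300, 500), segs,
                              c("Active TSS", "Bivalent/Poised TSS")), "Active TSS")
  expect_true(is.na(majority_state(gi("chrT", 700, 800), segs)))
})

test_that("dip detection finds planted valleys and rejects monotone signal", {
  mk_signal <- function(vals, origin = 0L, bin = 25L) {
    n <- length(vals)
    bin_starts <- origin + (seq_len(n) - 1L) * bin
    coverage_track(tibble::tibble(chrom = "chrT", start = bin_starts,
                                  end = bin_starts + bin, value = vals),
                   "s", ".")
  }
  peak <- gi("chrT", 0, 1000)
  # shoulders ~10, valley 3 at the anchor
  mid <- (seq_len(40) - 0.5) * 25
  vals <- 10 - 7 * exp(-((mid - 500) / 80)^2 / 2)
  dip <- detect_dip(mk_signal(vals), peak, anchor = 500, min_depth_fraction = 0.3,
                    max_anchor_distance = 250, shoulder_window = 400)
  expect_false(is.null(dip))
  expect_lt(abs(dip$center - 500), 25)
  expect_gt(dip$depth_fraction, 0.6)

  expect_null(detect_dip(mk_signal(seq(1, 40)), peak, anchor = 500))
  expect_error(detect_dip(mk_signal(vals), peak, anchor = 2000), "anchor")
})

test_that("dips on noisy two-peak profiles match an exhaustive scan oracle", {
  withr::local_seed(606)
  hits <- 0
  for (i in 1:50) {
    valley <- 1000 + sample(0:400, 1)
    mid <- (seq_len(80) - 0.5) * 25
    vals <- 1 + 9 * exp(-((mid - (valley - 250)) / 100)^2 / 2) +
      9 * exp(-((mid - (valley + 250)) / 100)^2 / 2) +
      stats::rnorm(80, 0, 0.05)
    vals <- pmax(vals, 0)
    sig <- coverage_track(tibble::tibble(chrom = "chrT",
                                         start = (seq_len(80) - 1L) * 25L,
                                         end = seq_len(80) * 25L, value = vals),
                          "s", ".")
    peak <- gi("chrT", 0, 2000)
    dip <- detect_dip(sig, peak, anchor = valley, min_depth_fraction = 0.3,
                      max_anchor_distance = 250, shoulder_window = 1000)
    # exhaustive-scan oracle for the minimum near the anchor
    near <- which(abs(mid - valley) <= 250)
    omin <- min(vals[near])
    ocenter <- mid[near][which(vals[near] == omin)][1]
    if (!is.null(dip)) {
      expect_equal(dip$center, ocenter)
      # depth inequality holds on re-evaluation
      left <- max(vals[mid < dip$center & mid >= dip$center - 1000])
      right <- max(vals[mid > dip$center & mid <= dip$center + 1000])
      expect_lte(omin, 0.7 * min(left, right))
      if (abs(dip$center - valley) <= 25) hits <- hits + 1
    }
  }
  expect_gte(hits, 48)  # >= 95% of planted dips recovered within one bin
})

test_that("poised-to-active transition index scans the sample order", {
  states <- list(ESC = "Bivalent/Poised TSS", iPSC = "Bivalent/Poised TSS",
                 NPC = "Active TSS")
  ord <- c("ESC", "iPSC", "NPC")
  expect_equal(state_transition(states, ord), 2L)
  expect_true(is.na(state_transition(list(ESC = "Active TSS", iPSC = "Active TSS"),
                                     c("ESC", "iPSC"))))
  expect_warning(
    idx <- state_transition(states[c("ESC", "NPC")], ord), "skipped")
  expect_equal(idx, 2L)
  # random label sequences equal a linear-scan oracle
  withr::local_seed(42)
  labs <- c("Bivalent/Poised TSS", "Active TSS", "Quies", "Enhancer")
  poised <- "Bivalent/Poised TSS"
  active <- c("Active TSS", "Enhancer")
  for (i in 1:100) {
    n <- sample(2:6, 1)
    s <- sample(labs, n, replace = TRUE)
    names(s) <- sprintf("s%d", 1:n)
    got <- state_transition(as.list(s), names(s), poised, active)
    want <- NA_integer_
    seen <- FALSE
    for (j in seq_len(n)) {
      if (seen && s[j] %in% active) { want <- j - 1L; break }
      if (s[j] %in% poised) seen <- TRUE
    }
    expect_identical(got, want)
  }
})
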