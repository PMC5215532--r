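elements2 <- tibble::tibble(element_id = c("RE01", "RE02"), chrom = "chrT",
                            start = c(150L, 5000L), end = c(400L, 5600L))

test_that("TF peak overlap sums intersections per (tf, element)", {
  pk <- tibble::tibble(chrom = "chrT", start = c(100L, 300L, 9000L),
                       end = c(200L, 380L, 9100L), tf = c("TF1", "TF1", "TF2"))
  ev <- overlap_tf_peaks(elements2, pk)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$tf, "TF1")
  expect_equal(ev$overlap_bp, 50L + 80L)
  expect_equal(ev$n_peaks, 2L)

  withr::local_seed(31)
  for (i in 1:20) {
    els <- tibble::tibble(element_id = sprintf("E%d", 1:5), chrom = "chrT",
                          start = sort(sample(seq(0, 9000, by = 100), 5)))
    els$end <- els$start + sample(100:800, 5, replace = TRUE)
    pks <- tibble::tibble(chrom = "chrT",
                          start = sample(0:9500, 15),
                          tf = sample(c("A", "B", "C"), 15, replace = TRUE))
    pks$end <- pks$start + sample(50:400, 15, replace = TRUE)
    got <- overlap_tf_peaks(els, pks)
    # pairwise intersection oracle
    want <- list()
    for (t in unique(pks$tf)) {
      for (e in seq_len(5)) {
        ov <- 0L; np <- 0L
        sub <- pks[pks$tf == t, ]
        for (p in seq_len(nrow(sub))) {
          o <- min(sub$end[p], els$end[e]) - max(sub$start[p], els$start[e])
          if (o >= 1) { ov <- ov + o; np <- np + 1L }
        }
        if (np > 0) want[[paste(t, e)]] <- c(ov, np)
      }
    }
    expect_equal(nrow(got), length(want))
    for (k in seq_len(nrow(got))) {
      key <- paste(got$tf[k], match(got$element_id[k], els$element_id))
      expect_equal(c(got$overlap_bp[k], got$n_peaks[k]),
                   stats::setNames(want[[key]], NULL))
    }
  }
})

test_that("expression contrast computes pseudocounted log2 fold changes", {
  tab <- tibble::tibble(gene = c("g1", "g2"), a1 = c(10, 5), a2 = c(10, 5),
                        b1 = c(40, 5), b2 = c(40, 5))
  ct <- expression_contrast(tab, c("a1", "a2"), c("b1", "b2"), pseudocount = 1)
  expect_equal(ct$log2fc[1], log2(41 / 11))
  expect_equal(ct$log2fc[2], 0)
  expect_error(expression_contrast(tab, "a1", "zz"), "unknown sample")
  expect_error(expression_contrast(tab, "a1", "a1"), "disjoint")

  withr::local_seed(202)
  for (i in 1:20) {
    tab2 <- tibble::tibble(gene = sprintf("g%d", 1:10))
    for (s in c("x1", "x2", "x3", "y1", "y2")) tab2[[s]] <- stats::rexp(10, 1 / 10)
    pc <- stats::runif(1, 0.5, 2)
    got <- expression_contrast(tab2, c("x1", "x2", "x3"), c("y1", "y2"), pc)
    want <- log2((rowMeans(tab2[, c("y1", "y2")]) + pc) /
                   (rowMeans(tab2[, c("x1", "x2", "x3")]) + pc))
    expect_equal(got$log2fc, unname(want))
  }
})

test_that("candidate ranking intersects binding with differential expression", {
  binding <- tibble::tibble(tf = c("TF1", "TF2", "TF3"),
                            element_id = "RE01", overlap_bp = 100L, n_peaks = 1L)
  contrasts <- tibble::tibble(gene = c("TF2", "TF3", "TF4"),
                              log2fc = c(2.0, -1.5, 3.0),
                              mean_b = c(10, 10, 10))
  got <- candidate_tfs(binding, contrasts, min_abs_log2fc = 1.0)
  expect_equal(got$tf, c("TF2", "TF3"))
  expect_equal(got$rank, 1:2)

  fam <- candidate_tfs(
    tibble::tibble(tf = c("FOXP2", "EGR1"), element_id = "RE01",
                   overlap_bp = 10L, n_peaks = 1L),
    tibble::tibble(gene = c("FOXP2", "EGR1"), log2fc = c(2, 3), mean_b = c(5, 5)),
    family_prefixes = "FOX")
  expect_equal(fam$tf, "FOXP2")

  # the actively-transcribed floor removes silent genes
  low <- candidate_tfs(binding,
                       tibble::tibble(gene = "TF2", log2fc = -4, mean_b = 0.2),
                       min_expression = 1)
  expect_equal(nrow(low), 0)
})

test_that("ranking is a set intersection, stable, and monotone in the cutoff", {
  withr::local_seed(44)
  for (i in 1:20) {
    tfs <- sprintf("TF%02d", 1:12)
    bound <- sample(tfs, sample(3:10, 1))
    binding <- tibble::tibble(tf = bound, element_id = "RE01",
                              overlap_bp = sample(10:500, length(bound)),
                              n_peaks = 1L)
    contrasts <- tibble::tibble(gene = sample(tfs, 9),
                                log2fc = round(stats::rnorm(9, 0, 2), 3),
                                mean_b = stats::rexp(9, 1 / 10) + 1)
    thr <- stats::runif(1, 0.5, 2)
    got <- candidate_tfs(binding, contrasts, min_abs_log2fc = thr)
    want <- intersect(bound, contrasts$gene[abs(contrasts$log2fc) >= thr])
    expect_setequal(got$tf, want)
    expect_equal(got$rank, seq_len(nrow(got)))
    # sorted by |log2fc| descending
    expect_true(all(diff(abs(got$log2fc)) <= 1e-12))
    # shuffling input row order leaves the ranking unchanged
    got2 <- candidate_tfs(binding[sample(nrow(binding)), ],
                          contrasts[sample(9), ], min_abs_log2fc = thr)
    expect_equal(got2, got)
    # raising the cutoff never adds candidates
    expect_true(all(candidate_tfs(binding, contrasts, thr + 0.5)$tf %in% got$tf))
  }
})
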