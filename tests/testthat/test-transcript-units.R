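track_from_runs <- function(runs, strand = "+", sample = "s1") {
  coverage_track(dplyr::mutate(runs, chrom = "chrT"), sample, strand)
}

test_that("call_units finds single runs and bridges forced gaps", {
  tr <- track_from_runs(tibble::tibble(start = 0L, end = 1000L, value = 5))
  u <- call_units(tr, min_cov = 1, max_gap = 100, min_len = 200)
  expect_equal(nrow(u), 1)
  expect_equal(c(u$start, u$end), c(0L, 1000L))
  expect_equal(u$mean_cov, 5)

  tr2 <- track_from_runs(tibble::tibble(start = c(0L, 450L), end = c(400L, 1000L),
                                        value = c(5, 5)))
  u2 <- call_units(tr2, min_cov = 1, max_gap = 100, min_len = 200)
  expect_equal(nrow(u2), 1)
  expect_equal(c(u2$start, u2$end), c(0L, 1000L))
  # gap 50 > max_gap 20: two units, short one filtered by min_len
  u3 <- call_units(tr2, min_cov = 1, max_gap = 20, min_len = 500)
  expect_equal(nrow(u3), 1)
  expect_equal(u3$start, 450L)
})

test_that("call_units equals the base-wise oracle on random tracks", {
  withr::local_seed(2001)
  for (i in 1:60) {
    fx <- random_track_fixture(len = 2500, lambda = stats::runif(1, 0.5, 3))
    min_cov <- sample(1:3, 1)
    max_gap <- sample(c(0L, 5L, 20L, 80L), 1)
    min_len <- sample(c(1L, 10L, 50L, 200L), 1)
    got <- call_units(fx$track, min_cov, max_gap, min_len)
    want <- oracle_call_units(fx$values, min_cov, max_gap, min_len)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
  }
})

test_that("units are disjoint, sorted, and scale-equivariant", {
  withr::local_seed(303)
  for (i in 1:20) {
    fx <- random_track_fixture(len = 2000)
    u <- call_units(fx$track, 1, 30, 20)
    if (nrow(u) > 1) {
      expect_true(all(diff(u$start) > 0))
      expect_true(all(u$start[-1] >= u$end[-nrow(u)]))
      expect_true(all(u$start[-1] - u$end[-nrow(u)] > 30))
    }
    # doubling coverage and min_cov leaves boundaries unchanged
    tr2 <- coverage_track(dplyr::mutate(fx$track$runs, value = value * 2),
                          fx$track$sample_id, fx$track$strand)
    u2 <- call_units(tr2, 2, 30, 20)
    expect_equal(u2[, c("start", "end")], u[, c("start", "end")])
    expect_equal(u2$mean_cov, u$mean_cov * 2)
  }
})

test_that("miRNA loci join units by containment and strand", {
  units <- tibble::tibble(unit_id = c("TU01", "TU02"), chrom = "chrT",
                          start = c(0L, 5000L), end = c(1000L, 9000L),
                          strand = c("+", "-"))
  loci <- gi("chrT", c(100, 800, 200, 6000, 950), c(122, 822, 222, 6022, 1050),
             c("+", "+", "-", "-", "+"),
             c("m1", "m2", "m_anti", "m3", "m_span"))
  res <- assign_mirnas(units, loci)
  expect_equal(res$assignments$name, c("m1", "m2", "m3"))
  poly <- res$polycistrons
  expect_true(poly$polycistronic[poly$unit_id == "TU01"])
  expect_false(poly$polycistronic[poly$unit_id == "TU02"])
  # antisense locus and boundary-spanning locus stay unassigned
  expect_setequal(res$unassigned$name, c("m_anti", "m_span"))
})

test_that("nine loci over three units match a brute-force containment oracle", {
  withr::local_seed(77)
  units <- tibble::tibble(unit_id = sprintf("TU%02d", 1:3), chrom = "chrT",
                          start = c(0L, 20000L, 50000L),
                          end = c(12000L, 45000L, 90000L),
                          strand = c("+", "-", "+"))
  st <- sample(0:89000, 9)
  loci <- gi("chrT", st, st + 80, sample(c("+", "-"), 9, replace = TRUE),
             sprintf("mir%02d", 1:9))
  res <- assign_mirnas(units, loci)
  expected <- character(0)
  for (i in 1:9) {
    for (j in 1:3) {
      if (loci$start[i] >= units$start[j] && loci$end[i] <= units$end[j] &&
          loci$strand[i] == units$strand[j]) {
        expected <- c(expected, paste(units$unit_id[j], loci$name[i]))
      }
    }
  }
  expect_setequal(paste(res$assignments$unit_id, res$assignments$name), expected)
  expect_equal(nrow(res$assignments) + nrow(res$unassigned), 9)
})

test_that("unit abundance matches its closed form and a brute-force sum", {
  tr <- track_from_runs(tibble::tibble(start = 0L, end = 1000L, value = 1))
  u <- tibble::tibble(unit_id = "TU01", chrom = "chrT", start = 0L, end = 1000L)
  expect_equal(unit_abundance(tr, u, 1e6)$abundance, 1000)
  empty <- track_from_runs(tibble::tibble(start = 2000L, end = 2100L, value = 1))
  expect_equal(unit_abundance(empty, u, 1e6)$abundance, 0)
  expect_error(unit_abundance(tr, u, 0), "positive")

  withr::local_seed(8)
  fx <- random_track_fixture(len = 3000)
  u2 <- tibble::tibble(unit_id = "TU01", chrom = "chrT", start = 250L, end = 2750L)
  got <- unit_abundance(fx$track, u2, 2e6)$abundance
  want <- sum(fx$values[251:2750]) / (2500 / 1000) / 2
  expect_equal(got, want)
})
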