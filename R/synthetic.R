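# Deterministic synthetic scenario with ground truth. The generator writes
# exactly the text formats the pipeline consumes (bedGraph, BED, FASTA, TSV,
# YAML config) -- no in-memory handoff -- so I/O is exercised end to end.

#' Default synthetic-scenario configuration
#'
#' The default scenario emulates the structure of the real inputs: a 1 Mb
#' chromosome carrying one dynamic unit (silent through the pluripotent
#' stages, expressed in tissue-derived NPCs, 20x background) and one
#' antisense constitutive unit (10x background in every sample); a bivalent
#' (poised) promoter and an alternative active promoter at the dynamic TSS;
#' a distal enhancer 10 kb upstream with p300 and a localized acetylation
#' dip at its DNase summit; two decoys each violating exactly one calling
#' condition; three planted forkhead-box motif words inside conserved
#' islands; and regulator/null TFs with a matching expression table.
#' Coverage noise is Poisson per 10 bp bin.
#'
#' @param seed Integer seed; a fixed seed reproduces every file byte for
#'   byte.
#' @param chrom_length Chromosome length (bp).
#' @param samples Ordered sample labels (differentiation order).
#' @param bg_rate Background Poisson rate per coverage bin.
#' @param unit_rate Signal rate per bin for a multiplier-1 unit (10x
#'   background).
#' @param dynamic_fold Expressed-sample fold of the dynamic unit over
#'   background.
#' @param library_size Library-size constant used for abundance
#'   normalization in the generated run config (chosen so that background
#'   regions fall below the dynamics expression floor of 1 while unit
#'   bodies sit in the single digits).
#' @param cov_bin,signal_bin Bin widths (bp) for coverage and binned
#'   acetylation signal.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 7L,
                            chrom_length = 1000000L,
                            samples = c("ESC", "iPSC", "PSC_NPC", "tissue_NPC"),
                            bg_rate = 0.1,
                            unit_rate = 1.0,
                            dynamic_fold = 20,
                            library_size = 5e8,
                            cov_bin = 10L,
                            signal_bin = 25L) {
  stopifnot(length(samples) >= 2, bg_rate > 0, unit_rate > bg_rate,
            chrom_length >= 7e5)  # planted coordinates need this much room
  chrom <- "chrS"
  expressing <- samples[length(samples)]
  dyn_mult <- stats::setNames(rep(0, length(samples)), samples)
  dyn_mult[expressing] <- dynamic_fold * bg_rate / unit_rate
  con_mult <- stats::setNames(rep(1, length(samples)), samples)
  units <- list(
    dyn = list(unit = "dyn", start = 300000L, end = 360000L, strand = "+",
               class = "dynamic", multipliers = as.list(dyn_mult)),
    con = list(unit = "con", start = 600000L, end = 680000L, strand = "-",
               class = "constitutive", multipliers = as.list(con_mult))
  )
  tss <- units$dyn$start
  early <- setdiff(samples, expressing)
  elements <- list(
    promoter_poised = list(
      kind = "promoter_poised", start = tss - 400L, end = tss + 400L,
      active_samples = expressing,
      extra_marks = list(list(assay = "H3K4me3", samples = early[1:2])),
      repressive = list(assay = "H3K27me3", samples = early,
                        start = tss - 600L, end = tss + 600L),
      states = list(early = "Bivalent/Poised TSS", late = "Active TSS"),
      transition_index = length(samples) - 1L
    ),
    promoter_active = list(
      kind = "promoter_active", start = tss + 1200L, end = tss + 1800L,
      active_samples = expressing,
      repressive = list(assay = "H3K27me3", samples = early[1:2],
                        start = tss + 1000L, end = tss + 2000L),
      states = list(early = "Quies", late = "Active TSS"),
      transition_index = NA_integer_
    ),
    enhancer = list(
      kind = "enhancer", start = tss - 10500L, end = tss - 9500L,
      active_samples = expressing,
      k27ac_broad = c(tss - 10700L, tss - 9300L),
      dnase = c(tss - 10200L, tss - 9800L),
      p300 = c(tss - 10150L, tss - 9850L),
      repressive = list(assay = "H3K9me3", samples = early[1:2],
                        start = tss - 10800L, end = tss - 9200L),
      states = list(early = "Quies", late = "Enhancer"),
      transition_index = NA_integer_
    )
  )
  decoys <- list(
    no_dnase = list(kind = "decoy_no_dnase", start = tss - 19000L,
                    end = tss - 18400L, missing = "DNase"),
    no_repressive = list(kind = "decoy_no_repressive", start = 330000L,
                         end = 330600L, missing = "repressive")
  )
  motif_words <- c("AAATATTGACTC", "CATTGTTTGCTT", "AAATATTGGTTC")
  motif_instances <- tibble::tibble(
    start = c(tss - 10400L, tss - 10050L, tss - 9700L),
    end = c(tss - 10400L, tss - 10050L, tss - 9700L) + 12L,
    strand = "+", word = motif_words
  )
  regulators <- list(
    FOXP2 = list(mean_a = 5, mean_b = 40, peaks = list(c(tss - 10150L, tss - 9900L))),
    TFAP2C = list(mean_a = 30, mean_b = 4, peaks = list(c(tss - 300L, tss + 300L)))
  )
  null_tfs <- list(
    CTCF = list(mean_a = 20, mean_b = 20, peaks = list(c(tss + 1250L, tss + 1500L))),
    EGR1 = list(mean_a = 10, mean_b = 12, peaks = list(c(tss + 1300L, tss + 1450L))),
    PAX6 = list(mean_a = 2, mean_b = 30, peaks = list()),
    NANOG = list(mean_a = 15, mean_b = 12, peaks = list(c(500000L, 500200L)))
  )
  structure(list(
    seed = as.integer(seed), chrom = chrom, chrom_length = as.integer(chrom_length),
    samples = samples, expressing = expressing,
    bg_rate = bg_rate, unit_rate = unit_rate, dynamic_fold = dynamic_fold,
    library_size = library_size, cov_bin = as.integer(cov_bin),
    signal_bin = as.integer(signal_bin), peak_jitter = 40L,
    units = units, elements = elements, decoys = decoys,
    motif_instances = motif_instances,
    island_flank = 20L, island_score = 0.95, bg_conservation = 0.2,
    regulators = regulators, null_tfs = null_tfs, n_reps = 3L,
    state_vocabulary = c("Active TSS", "Flanking active TSS",
                         "Bivalent/Poised TSS", "Enhancer", "Genic Enhancer",
                         "Bivalent Enhancer", "Tx", "Quies")
  ), class = "scenario_config")
}

.write_fasta <- function(seq_chr, name, path, width = 70L) {
  n <- nchar(seq_chr)
  starts <- seq(1L, n, by = width)
  lines <- substring(seq_chr, starts, pmin(starts + width - 1L, n))
  writeLines(c(paste0(">", name), lines), path)
}

.write_bedgraph_runs <- function(runs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", runs$chrom, runs$start, runs$end,
                   format(runs$value, trim = TRUE, scientific = FALSE, digits = 12))
  writeLines(lines, path)
}

.write_bed6 <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, name, strand),
             path)
}

.jitter1 <- function(j) sample.int(2L * j + 1L, 1L) - j - 1L

#' Generate the synthetic scenario
#'
#' Writes the full input set for one pipeline run -- genome FASTA with
#' planted motif words, per-sample stranded coverage bedGraphs, per
#' sample-by-assay peak BEDs consistent with the expression pattern,
#' chromatin-state BEDs, binned acetylation signal with a valley at the
#' enhancer's DNase summit, a conservation bedGraph with high-scoring
#' islands over the motif instances, mature-miRNA loci, TF peak BEDs, an
#' expression table -- plus `manifest.json` (ground truth) and `config.yaml`
#' (a ready-to-run pipeline configuration with paths relative to the output
#' directory, so identical seeds give byte-identical trees anywhere).
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @return The ground-truth manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
generate_scenario <- function(cfg = scenario_config(), out_dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("coverage", "peaks", "states", "signal", "tf_peaks")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  withr::local_seed(cfg$seed)
  L <- cfg$chrom_length
  chrom <- cfg$chrom

  ## genome with planted motif words
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (i in seq_len(nrow(cfg$motif_instances))) {
    w <- strsplit(cfg$motif_instances$word[i], "")[[1]]
    bases[(cfg$motif_instances$start[i] + 1L):cfg$motif_instances$end[i]] <- w
  }
  .write_fasta(paste(bases, collapse = ""), chrom, file.path(out_dir, "genome.fa"))

  ## stranded coverage per sample: Poisson per cov_bin
  n_bins <- L %/% cfg$cov_bin
  bin_start <- (seq_len(n_bins) - 1L) * cfg$cov_bin
  coverage_files <- list()
  for (s in cfg$samples) {
    for (str in c("+", "-")) {
      rate <- rep(cfg$bg_rate, n_bins)
      for (u in cfg$units) {
        if (u$strand != str) next
        idx <- which(bin_start >= u$start & bin_start < u$end)
        rate[idx] <- rate[idx] + cfg$unit_rate * u$multipliers[[s]]
      }
      val <- stats::rpois(n_bins, rate)
      nz <- which(val > 0)
      runs <- tibble::tibble(chrom = chrom, start = bin_start[nz],
                             end = bin_start[nz] + cfg$cov_bin, value = val[nz])
      fn <- sprintf("coverage/%s.%s.bedgraph", s, if (str == "+") "plus" else "minus")
      .write_bedgraph_runs(runs, file.path(out_dir, fn))
      coverage_files[[length(coverage_files) + 1L]] <-
        list(sample = s, strand = str, path = fn)
    }
  }

  ## peaks per sample x assay
  jit <- function(a, b) {
    c(max(0L, a + .jitter1(cfg$peak_jitter)), min(L, b + .jitter1(cfg$peak_jitter)))
  }
  peak_rows <- list()
  add_peak <- function(sample, assay, a, b, jittered = TRUE) {
    iv <- if (jittered) jit(a, b) else c(a, b)
    peak_rows[[length(peak_rows) + 1L]] <<-
      tibble::tibble(chrom = chrom, start = iv[1], end = iv[2],
                     sample_id = sample, assay = assay)
  }
  for (el in cfg$elements) {
    for (s in el$active_samples) {
      k27 <- if (!is.null(el$k27ac_broad)) el$k27ac_broad else c(el$start, el$end)
      add_peak(s, "H3K27ac", k27[1], k27[2])
      add_peak(s, "H3K4me3", el$start, el$end)
      dn <- if (!is.null(el$dnase)) el$dnase else c(el$start, el$end)
      add_peak(s, "DNase", dn[1], dn[2])
      if (!is.null(el$p300)) add_peak(s, "p300", el$p300[1], el$p300[2])
    }
    if (!is.null(el$extra_marks)) {
      for (em in el$extra_marks) {
        for (s in em$samples) add_peak(s, em$assay, el$start, el$end)
      }
    }
    if (!is.null(el$repressive)) {
      for (s in el$repressive$samples) {
        add_peak(s, el$repressive$assay, el$repressive$start, el$repressive$end)
      }
    }
  }
  for (dc in cfg$decoys) {
    marks <- setdiff(c("H3K27ac", "H3K4me3", "DNase"), dc$missing)
    for (a in marks) add_peak(cfg$expressing, a, dc$start, dc$end)
    if (dc$missing != "repressive") {
      add_peak(cfg$samples[1], "H3K27me3", dc$start - 100L, dc$end + 100L)
    }
  }
  # constitutive unit promoter: active marks in every sample, no repressive
  con <- cfg$units$con
  con_tss <- if (con$strand == "+") con$start else con$end
  for (s in cfg$samples) {
    add_peak(s, "H3K27ac", con_tss - 400L, con_tss + 400L)
    add_peak(s, "H3K4me3", con_tss - 400L, con_tss + 400L)
    add_peak(s, "DNase", con_tss - 300L, con_tss + 300L)
  }
  peaks <- dplyr::bind_rows(peak_rows)
  peak_files <- list()
  for (key in unique(paste(peaks$sample_id, peaks$assay))) {
    parts <- strsplit(key, " ")[[1]]
    sub <- peaks[peaks$sample_id == parts[1] & peaks$assay == parts[2], , drop = FALSE] |>
      dplyr::arrange(.data$start)
    fn <- sprintf("peaks/%s.%s.bed", parts[1], parts[2])
    .write_bed6(sub, file.path(out_dir, fn))
    peak_files[[length(peak_files) + 1L]] <-
      list(sample = parts[1], assay = parts[2], path = fn)
  }

  ## chromatin-state tilings
  state_files <- list()
  late <- cfg$expressing
  for (s in cfg$samples) {
    phase <- if (s == late) "late" else "early"
    regions <- list()
    for (el in cfg$elements) {
      regions[[length(regions) + 1L]] <-
        tibble::tibble(start = el$start, end = el$end, state = el$states[[phase]])
    }
    if (s == late) {
      regions[[length(regions) + 1L]] <-
        tibble::tibble(start = cfg$elements$promoter_active$end,
                       end = cfg$units$dyn$end, state = "Tx")
    }
    regions[[length(regions) + 1L]] <-
      tibble::tibble(start = con$start, end = con_tss - 400L, state = "Tx")
    regions[[length(regions) + 1L]] <-
      tibble::tibble(start = con_tss - 400L, end = con_tss + 400L, state = "Active TSS")
    reg <- dplyr::bind_rows(regions) |>
      dplyr::filter(.data$state != "Quies") |>
      dplyr::arrange(.data$start)
    segs <- list()
    pos <- 0L
    for (i in seq_len(nrow(reg))) {
      if (reg$start[i] > pos) {
        segs[[length(segs) + 1L]] <-
          tibble::tibble(start = pos, end = reg$start[i], state = "Quies")
      }
      segs[[length(segs) + 1L]] <- reg[i, ]
      pos <- reg$end[i]
    }
    if (pos < L) {
      segs[[length(segs) + 1L]] <- tibble::tibble(start = pos, end = L, state = "Quies")
    }
    tiles <- dplyr::bind_rows(segs) |>
      dplyr::mutate(chrom = chrom, name = .data$state)
    fn <- sprintf("states/%s.states.bed", s)
    .write_bed6(tiles[, c("chrom", "start", "end", "name")], file.path(out_dir, fn))
    state_files[[length(state_files) + 1L]] <- list(sample = s, path = fn)
  }

  ## binned acetylation signal with a valley at the enhancer DNase summit
  enh <- cfg$elements$enhancer
  dip_center <- as.integer(mean(enh$dnase))
  span <- c(enh$k27ac_broad[1], enh$k27ac_broad[2])
  bs <- seq(span[1], span[2] - 1L, by = cfg$signal_bin)
  mid <- bs + cfg$signal_bin / 2
  peak_sd <- 120
  shoulder_off <- 300
  sigval <- 1 + 10 * exp(-((mid - (dip_center - shoulder_off)) / peak_sd)^2 / 2) +
    10 * exp(-((mid - (dip_center + shoulder_off)) / peak_sd)^2 / 2) +
    stats::rnorm(length(mid), 0, 0.05)
  sigval <- round(pmax(sigval, 0), 3)
  .write_bedgraph_runs(
    tibble::tibble(chrom = chrom, start = bs, end = bs + cfg$signal_bin,
                   value = sigval),
    file.path(out_dir, "signal/H3K27ac.binned.bedgraph")
  )

  ## conservation: background everywhere, islands over motif instances
  isl <- tibble::tibble(start = cfg$motif_instances$start - cfg$island_flank,
                        end = cfg$motif_instances$end + cfg$island_flank)
  cons <- list()
  pos <- 0L
  for (i in seq_len(nrow(isl))) {
    if (isl$start[i] > pos) {
      cons[[length(cons) + 1L]] <- tibble::tibble(start = pos, end = isl$start[i],
                                                  value = cfg$bg_conservation)
    }
    cons[[length(cons) + 1L]] <- tibble::tibble(start = isl$start[i], end = isl$end[i],
                                                value = cfg$island_score)
    pos <- isl$end[i]
  }
  cons[[length(cons) + 1L]] <- tibble::tibble(start = pos, end = L,
                                              value = cfg$bg_conservation)
  .write_bedgraph_runs(dplyr::bind_rows(cons) |> dplyr::mutate(chrom = chrom),
                       file.path(out_dir, "conservation.bedgraph"))

  ## mature-miRNA loci
  dyn <- cfg$units$dyn
  mirna <- tibble::tibble(
    chrom = chrom,
    start = c(310000L, 340000L, 610000L, 630000L, 650000L, 320000L),
    end = c(310000L, 340000L, 610000L, 630000L, 650000L, 320000L) + 80L,
    name = c("mir_dyn_a", "mir_dyn_b", "mir_con_a", "mir_con_b", "mir_con_c",
             "mir_orphan"),
    strand = c("+", "+", "-", "-", "-", "-")
  )
  .write_bed6(mirna, file.path(out_dir, "mirna_loci.bed"))

  ## expression table (two conditions, n_reps replicates each)
  tf_specs <- c(cfg$regulators, cfg$null_tfs)
  fillers <- paste0("GENE", sprintf("%02d", 1:6))
  filler_means <- stats::runif(length(fillers), 2, 30)
  genes <- c(names(tf_specs), fillers)
  mean_a <- c(purrr::map_dbl(tf_specs, "mean_a"), filler_means)
  mean_b <- c(purrr::map_dbl(tf_specs, "mean_b"), filler_means)
  cond_a <- paste0("PSC_NPC_r", seq_len(cfg$n_reps))
  cond_b <- paste0("tissue_NPC_r", seq_len(cfg$n_reps))
  vals_a <- outer(mean_a, rep(1, cfg$n_reps)) *
    exp(matrix(stats::rnorm(length(genes) * cfg$n_reps, 0, 0.08), ncol = cfg$n_reps))
  vals_b <- outer(mean_b, rep(1, cfg$n_reps)) *
    exp(matrix(stats::rnorm(length(genes) * cfg$n_reps, 0, 0.08), ncol = cfg$n_reps))
  expr <- tibble::as_tibble(round(cbind(vals_a, vals_b), 3),
                            .name_repair = ~ c(cond_a, cond_b))
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes), expr)
  readr::write_tsv(expr, file.path(out_dir, "expression.tsv"), progress = FALSE)

  ## TF peak BEDs
  tf_files <- list()
  for (tf in names(tf_specs)) {
    pk <- tf_specs[[tf]]$peaks
    if (length(pk) == 0) next
    tb <- dplyr::bind_rows(purrr::map(pk, ~ tibble::tibble(chrom = chrom,
                                                           start = .x[1], end = .x[2])))
    fn <- sprintf("tf_peaks/%s.bed", tf)
    .write_bed6(tb, file.path(out_dir, fn))
    tf_files[[length(tf_files) + 1L]] <- list(tf = tf, path = fn)
  }

  ## ground-truth manifest
  manifest <- list(
    seed = cfg$seed, chrom = chrom, chrom_length = L,
    samples = cfg$samples, library_size = cfg$library_size,
    units = purrr::map(cfg$units, function(u) {
      list(unit = u$unit, start = u$start, end = u$end, strand = u$strand,
           class = u$class,
           expressing = cfg$samples[purrr::map_dbl(u$multipliers[cfg$samples],
                                                   identity) > 0])
    }),
    elements = purrr::map(cfg$elements, function(el) {
      list(kind = el$kind, start = el$start, end = el$end,
           midpoint = (el$start + el$end) / 2,
           transition_index = el$transition_index)
    }),
    decoys = purrr::map(cfg$decoys, function(dc) {
      list(kind = dc$kind, start = dc$start, end = dc$end, missing = dc$missing)
    }),
    dip = list(center = dip_center, anchor = dip_center),
    motif_instances = purrr::pmap(cfg$motif_instances,
                                  function(start, end, strand, word) {
                                    list(start = start, end = end,
                                         strand = strand, word = word)
                                  }),
    islands = purrr::pmap(isl, function(start, end) list(start = start, end = end)),
    regulators = names(cfg$regulators),
    expression_conditions = list(cond_a = cond_a, cond_b = cond_b),
    counts = list(units = length(cfg$units), dynamic = 1L, constitutive = 1L,
                  elements = length(cfg$elements), decoys = length(cfg$decoys),
                  motif_instances = nrow(cfg$motif_instances),
                  regulators = length(cfg$regulators))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## ready-to-run pipeline config (paths relative to out_dir)
  run_cfg <- list(
    samples = as.list(cfg$samples),
    chrom_length = L,
    genome = "genome.fa",
    mirna_loci = "mirna_loci.bed",
    conservation = "conservation.bedgraph",
    coverage = coverage_files,
    peaks = peak_files,
    states = state_files,
    state_vocabulary = as.list(cfg$state_vocabulary),
    acetyl_signal = list(sample = cfg$expressing, path = "signal/H3K27ac.binned.bedgraph"),
    expression = list(path = "expression.tsv", cond_a = as.list(cond_a),
                      cond_b = as.list(cond_b)),
    tf_peaks = tf_files,
    motifs = list(FOX = "[AC]A[AT]T[AG]TT[GT][AG][CT]T[CT]"),
    params = list(
      min_cov = 2, max_gap = 500L, min_len = 5000L,
      library_size = cfg$library_size,
      pseudocount = 0.5, fold_threshold = 4, expression_floor = 1,
      flank_bp = 20000L, merge_gap = 200L, min_expressing_support = 1L,
      require_repressive = TRUE, tss_distance_bp = 2000L,
      dip_min_depth_fraction = 0.3, dip_max_anchor_distance = 250L,
      dip_shoulder_window = 1000L,
      conservation_min_mean = 0.8,
      contrast_pseudocount = 1, min_abs_log2fc = 1, min_expression = 1
    )
  )
  yaml::write_yaml(run_cfg, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Build the synthetic expression table in memory
#'
#' Same contrast structure as the table written by [generate_scenario()]:
#' regulators differ >= 4x between the two conditions, nulls are flat,
#' values stay non-negative (log-normal replicate noise).
#'
#' @param cfg A [scenario_config()].
#' @return Tibble with `gene` plus replicate columns for both conditions.
#' @export
make_expression_table <- function(cfg = scenario_config()) {
  withr::local_seed(cfg$seed + 1L)
  tf_specs <- c(cfg$regulators, cfg$null_tfs)
  genes <- names(tf_specs)
  mean_a <- purrr::map_dbl(tf_specs, "mean_a")
  mean_b <- purrr::map_dbl(tf_specs, "mean_b")
  cond_a <- paste0("PSC_NPC_r", seq_len(cfg$n_reps))
  cond_b <- paste0("tissue_NPC_r", seq_len(cfg$n_reps))
  vals <- cbind(
    outer(mean_a, rep(1, cfg$n_reps)) *
      exp(matrix(stats::rnorm(length(genes) * cfg$n_reps, 0, 0.08), ncol = cfg$n_reps)),
    outer(mean_b, rep(1, cfg$n_reps)) *
      exp(matrix(stats::rnorm(length(genes) * cfg$n_reps, 0, 0.08), ncol = cfg$n_reps))
  )
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(round(vals, 3),
                                     .name_repair = ~ c(cond_a, cond_b)))
}
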