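# File-to-file pipeline stages and single-command orchestration.
# Every stage reads the products of the previous one from out_dir, so
# stage-wise execution equals the monolithic run product for product.

#' Read and validate a pipeline run configuration
#'
#' The YAML layout is the one written by [generate_scenario()]: input paths
#' keyed by (sample, assay), the ordered sample list, and a `params` block.
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Path to a YAML run configuration.
#' @return A validated `run_config` list with absolute paths and defaulted
#'   parameters.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("genome", "mirna_loci", "conservation")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- resolve(cfg[[key]])
  }
  cfg$coverage <- purrr::map(cfg$coverage, function(x) {
    x$path <- resolve(x$path); x
  })
  cfg$peaks <- purrr::map(cfg$peaks, function(x) {
    x$path <- resolve(x$path); x
  })
  cfg$states <- purrr::map(cfg$states, function(x) {
    x$path <- resolve(x$path); x
  })
  cfg$tf_peaks <- purrr::map(cfg$tf_peaks, function(x) {
    x$path <- resolve(x$path); x
  })
  if (!is.null(cfg$expression)) cfg$expression$path <- resolve(cfg$expression$path)
  if (!is.null(cfg$acetyl_signal)) cfg$acetyl_signal$path <- resolve(cfg$acetyl_signal$path)
  cfg$samples <- unlist(cfg$samples)
  defaults <- list(
    min_cov = 1.0, max_gap = 500L, min_len = 1000L, library_size = 1e6,
    pseudocount = 0.5, fold_threshold = 4, expression_floor = 1,
    flank_bp = 20000L, merge_gap = 200L, min_expressing_support = 1L,
    require_repressive = TRUE, tss_distance_bp = 2000L,
    dip_min_depth_fraction = 0.3, dip_max_anchor_distance = 250L,
    dip_shoulder_window = 1000L, conservation_min_mean = 0.8,
    contrast_pseudocount = 1, min_abs_log2fc = 1, min_expression = 1
  )
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  p <- cfg$params
  if (p$min_cov <= 0 || p$max_gap < 0 || p$min_len < 1 || p$library_size <= 0 ||
      p$flank_bp <= 0 || p$fold_threshold <= 1) {
    stop("read_run_config: parameter out of range", call. = FALSE)
  }
  for (x in c(cfg$coverage, cfg$peaks, cfg$states, cfg$tf_peaks)) {
    if (!file.exists(x$path)) {
      key <- paste(purrr::compact(x[c("sample", "assay", "strand", "tf")]),
                   collapse = ", ")
      stop(sprintf("missing input file for (%s): %s", key, x$path), call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

.load_coverage_tracks <- function(cfg) {
  purrr::map(cfg$coverage, function(x) {
    read_bedgraph(x$path, sample_id = x$sample, strand = x$strand)
  })
}

.load_peaks <- function(cfg) {
  dplyr::bind_rows(purrr::map(cfg$peaks, function(x) {
    b <- read_bed(x$path)
    if (nrow(b) == 0) return(NULL)
    dplyr::mutate(b[, c("chrom", "start", "end")], sample_id = x$sample,
                  assay = x$assay)
  }))
}

.load_states <- function(cfg) {
  dplyr::bind_rows(purrr::map(cfg$states, function(x) {
    read_state_bed(x$path, sample_id = x$sample,
                   vocabulary = unlist(cfg$state_vocabulary))
  }))
}

#' Stage: call and merge transcription units, compute abundances
#'
#' Products in `out_dir`: `units.gff3`, `units.tsv`, `abundance.tsv` (unit x
#' sample RPKM-style abundances, strand-matched track per sample).
#'
#' @param cfg A [read_run_config()] configuration.
#' @param out_dir Output directory.
#' @return List with `units`, `abundance`, `polycistrons` tibbles, invisibly.
#' @export
stage_units <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  tracks <- .load_coverage_tracks(cfg)
  per_sample <- dplyr::bind_rows(purrr::map(tracks, function(tr) {
    call_units(tr, min_cov = p$min_cov, max_gap = p$max_gap, min_len = p$min_len)
  }))
  units <- merge_unit_calls(per_sample)
  abundance <- dplyr::bind_rows(purrr::map(tracks, function(tr) {
    u <- units[units$strand == tr$strand, , drop = FALSE]
    unit_abundance(tr, u, library_size = p$library_size)
  })) |>
    dplyr::arrange(.data$unit_id, .data$sample_id)
  poly <- NULL
  units_out <- units
  if (!is.null(cfg$mirna_loci)) {
    mirna <- read_bed(cfg$mirna_loci)
    asn <- assign_mirnas(units, mirna)
    poly <- asn$polycistrons
    units_out <- dplyr::left_join(units, poly, by = "unit_id") |>
      dplyr::mutate(n_members = dplyr::coalesce(.data$n_members, 0L),
                    polycistronic = dplyr::coalesce(.data$polycistronic, FALSE))
  }
  readr::write_tsv(units_out, file.path(out_dir, "units.tsv"), progress = FALSE)
  readr::write_tsv(abundance, file.path(out_dir, "abundance.tsv"), progress = FALSE)
  gff <- dplyr::mutate(units_out, type = "transcription_unit") |>
    dplyr::rename(ID = "unit_id")
  write_gff3(gff, file.path(out_dir, "units.gff3"))
  invisible(list(units = units_out, abundance = abundance, polycistrons = poly))
}

#' Stage: classify unit dynamics
#'
#' Reads `abundance.tsv`, writes `dynamics.tsv` (per unit: `log2_range`,
#' `label`, comma-joined `expressing` set, `transition_index` in the
#' configured sample order).
#'
#' @inheritParams stage_units
#' @return The dynamics tibble, invisibly.
#' @export
stage_dynamics <- function(cfg, out_dir) {
  p <- cfg$params
  abundance <- readr::read_tsv(file.path(out_dir, "abundance.tsv"),
                               show_col_types = FALSE, progress = FALSE)
  calls <- classify_dynamics(abundance, pseudocount = p$pseudocount,
                             fold_threshold = p$fold_threshold,
                             expression_floor = p$expression_floor)
  order_idx <- purrr::map_int(calls$unit_id, function(uid) {
    ab <- abundance[abundance$unit_id == uid, , drop = FALSE]
    ab <- ab[match(cfg$samples, ab$sample_id), , drop = FALSE]
    order_transitions(ab$abundance, floor = p$expression_floor)
  })
  out <- calls |>
    dplyr::mutate(expressing = purrr::map_chr(.data$expressing, paste, collapse = ","),
                  transition_index = order_idx)
  readr::write_tsv(out, file.path(out_dir, "dynamics.tsv"), progress = FALSE)
  invisible(out)
}

#' Stage: assemble and classify regulatory elements
#'
#' For every unit, builds the flanking search window, colocalizes active
#' and repressive peak evidence using that unit's expressing-sample set,
#' classifies each candidate, records per-sample majority states and the
#' poised-to-active transition index, and attempts dip detection at the
#' DNase summit when binned acetylation signal is configured. Products:
#' `elements.tsv`, `elements.gff3`, `evidence.tsv`.
#'
#' @inheritParams stage_units
#' @return The elements tibble, invisibly.
#' @export
stage_elements <- function(cfg, out_dir) {
  p <- cfg$params
  units <- readr::read_tsv(file.path(out_dir, "units.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  dynamics <- readr::read_tsv(file.path(out_dir, "dynamics.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  peaks <- .load_peaks(cfg)
  states <- if (length(cfg$states) > 0) .load_states(cfg) else NULL
  signal <- if (!is.null(cfg$acetyl_signal)) {
    read_bedgraph(cfg$acetyl_signal$path, sample_id = cfg$acetyl_signal$sample)
  }
  ccfg <- coloc_config(flank_bp = p$flank_bp,
                       min_expressing_support = p$min_expressing_support,
                       require_repressive = p$require_repressive,
                       merge_gap = p$merge_gap)
  rows <- list()
  evidence <- list()
  for (i in seq_len(nrow(units))) {
    unit <- units[i, , drop = FALSE]
    dyn <- dynamics[dynamics$unit_id == unit$unit_id, , drop = FALSE]
    expressing <- strsplit(dyn$expressing %||% "", ",")[[1]]
    expressing <- expressing[nzchar(expressing)]
    if (length(expressing) == 0) next
    win <- search_window(unit, flank_bp = p$flank_bp,
                         chrom_length = cfg$chrom_length)
    cands <- colocalize(win, peaks, expressing, ccfg)
    for (j in seq_len(nrow(cands))) {
      el <- classify_element(cands[j, , drop = FALSE], unit, peaks,
                             states = states, tss_distance_bp = p$tss_distance_bp)
      st <- el$states[[1]]
      el$transition_index <- state_transition(st, cfg$samples)
      # dip detection at the DNase summit inside this candidate
      dipc <- NA_real_; dipd <- NA_real_
      if (!is.null(signal)) {
        dn <- peaks[peaks$assay == "DNase" & peaks$sample_id %in% expressing &
                      peaks$chrom == el$chrom & peaks$end > el$start &
                      peaks$start < el$end, , drop = FALSE]
        if (nrow(dn) > 0) {
          dn <- dn[order(dn$start), , drop = FALSE][1, ]
          anchor <- as.integer((dn$start + dn$end) / 2)
          ac <- peaks[peaks$assay == "H3K27ac" & peaks$sample_id %in% expressing &
                        peaks$chrom == el$chrom & peaks$start <= anchor &
                        peaks$end > anchor, , drop = FALSE]
          if (nrow(ac) > 0) {
            ac <- ac[order(ac$start), , drop = FALSE][1, ]
            spans <- any(signal$runs$chrom == ac$chrom &
                           signal$runs$end > ac$start & signal$runs$start < ac$end)
            if (spans) {
              dip <- detect_dip(signal, ac[, c("chrom", "start", "end")], anchor,
                                min_depth_fraction = p$dip_min_depth_fraction,
                                max_anchor_distance = p$dip_max_anchor_distance,
                                shoulder_window = p$dip_shoulder_window)
              if (!is.null(dip)) {
                dipc <- dip$center; dipd <- dip$depth_fraction
              }
            }
          }
        }
      }
      el$dip_center <- dipc
      el$dip_depth <- dipd
      rows[[length(rows) + 1L]] <- el
      # evidence ledger: overlap of every (sample, assay) peak set
      ovp <- peaks[peaks$chrom == el$chrom & peaks$end > el$start &
                     peaks$start < el$end, , drop = FALSE]
      if (nrow(ovp) > 0) {
        evidence[[length(evidence) + 1L]] <- ovp |>
          dplyr::mutate(ov = pmin(.data$end, el$end) - pmax(.data$start, el$start)) |>
          dplyr::group_by(.data$sample_id, .data$assay) |>
          dplyr::summarise(overlap_bp = sum(.data$ov), n_peaks = dplyr::n(),
                           .groups = "drop") |>
          dplyr::mutate(unit_id = el$unit_id, start = el$start, end = el$end)
      }
    }
  }
  elements <- dplyr::bind_rows(rows)
  if (nrow(elements) > 0) {
    elements <- dplyr::arrange(elements, .data$chrom, .data$start) |>
      dplyr::mutate(element_id = sprintf("RE%02d", dplyr::row_number())) |>
      dplyr::select("element_id", dplyr::everything())
    states_chr <- purrr::map_chr(elements$states, function(s) {
      if (length(s) == 0) return(NA_character_)
      s <- s[order(match(names(s), cfg$samples))]
      paste(sprintf("%s:%s", names(s), unlist(s)), collapse = "|")
    })
    flat <- dplyr::mutate(elements, states = states_chr)
  } else {
    flat <- tibble::tibble(element_id = character(), chrom = character(),
                           start = integer(), end = integer(), strand = character(),
                           unit_id = character(), category = character(),
                           p300 = logical(), distance_to_tss = integer(),
                           states = character(),
                           transition_index = integer(),
                           dip_center = numeric(), dip_depth = numeric())
  }
  readr::write_tsv(flat, file.path(out_dir, "elements.tsv"), progress = FALSE)
  ev <- dplyr::bind_rows(evidence)
  if (nrow(ev) > 0) {
    ev <- dplyr::left_join(ev,
                           flat[, c("element_id", "start", "end")],
                           by = c("start", "end")) |>
      dplyr::select("element_id", "sample_id", "assay", "overlap_bp", "n_peaks") |>
      dplyr::arrange(.data$element_id, .data$sample_id, .data$assay)
  } else {
    ev <- tibble::tibble(element_id = character(), sample_id = character(),
                         assay = character(), overlap_bp = integer(),
                         n_peaks = integer())
  }
  readr::write_tsv(ev, file.path(out_dir, "evidence.tsv"), progress = FALSE)
  gff <- flat |>
    dplyr::mutate(type = "regulatory_element") |>
    dplyr::rename(ID = "element_id") |>
    dplyr::select(-"states")
  write_gff3(gff, file.path(out_dir, "elements.gff3"))
  invisible(flat)
}

#' Stage: motif scanning and conservation filtering
#'
#' Scans every configured degenerate motif over every genome sequence on
#' both strands, applies the mean-conservation gate, and writes
#' `motif_hits.tsv` (all hits with `mean_conservation` and a `conserved`
#' flag) plus `motifs.bed` (BED6 of conserved hits).
#'
#' @inheritParams stage_units
#' @return Tibble of all hits with the `conserved` flag, invisibly.
#' @export
stage_motifs <- function(cfg, out_dir) {
  p <- cfg$params
  genome <- read_genome_fasta(cfg$genome)
  cons <- read_bedgraph(cfg$conservation, sample_id = "conservation")
  hits <- dplyr::bind_rows(purrr::imap(cfg$motifs, function(pattern, label) {
    motif <- parse_iupac(pattern, label)
    dplyr::bind_rows(purrr::imap(as.list(genome), function(seq, chr) {
      scan_iupac(seq, motif, both_strands = TRUE, chrom = chr)
    }))
  }))
  if (nrow(hits) == 0) {
    hits <- .hit_tbl()
  }
  kept <- conservation_filter(hits, cons, min_mean = p$conservation_min_mean)
  hits$mean_conservation <- purrr::pmap_dbl(
    hits[, c("chrom", "start", "end")],
    function(chrom, start, end) track_mean(cons, chrom, start, end)
  )
  hits$conserved <- hits$mean_conservation >= p$conservation_min_mean
  readr::write_tsv(hits, file.path(out_dir, "motif_hits.tsv"), progress = FALSE)
  write_hits_bed(kept, file.path(out_dir, "motifs.bed"))
  invisible(hits)
}

#' Stage: nominate candidate regulator TFs
#'
#' Reads `elements.tsv`, overlaps configured TF peak BEDs with the
#' elements, contrasts expression between the two configured conditions,
#' and writes the ranked `candidates.tsv`.
#'
#' @inheritParams stage_units
#' @return The ranked candidate tibble, invisibly.
#' @export
stage_tfs <- function(cfg, out_dir) {
  p <- cfg$params
  elements <- readr::read_tsv(file.path(out_dir, "elements.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  tf_peaks <- dplyr::bind_rows(purrr::map(cfg$tf_peaks, function(x) {
    b <- read_bed(x$path)
    if (nrow(b) == 0) return(NULL)
    dplyr::mutate(b[, c("chrom", "start", "end")], tf = x$tf)
  }))
  binding <- overlap_tf_peaks(elements, tf_peaks)
  expr <- read_expression_tsv(cfg$expression$path)
  contrasts <- expression_contrast(expr, unlist(cfg$expression$cond_a),
                                   unlist(cfg$expression$cond_b),
                                   pseudocount = p$contrast_pseudocount)
  cand <- candidate_tfs(binding, contrasts,
                        min_abs_log2fc = p$min_abs_log2fc,
                        family_prefixes = cfg$family_prefixes,
                        min_expression = p$min_expression)
  readr::write_tsv(cand, file.path(out_dir, "candidates.tsv"), progress = FALSE)
  invisible(cand)
}

#' Run the whole pipeline
#'
#' Executes unit calling, dynamics classification, regulatory-element
#' assembly, motif/conservation scanning and TF nomination in order, and
#' writes `summary.json` with keys `units`, `dynamics`, `elements`,
#' `motif_hits`, `candidates`. Stage-wise execution via the `stage_*`
#' functions produces identical products.
#'
#' @param config Path to a YAML run configuration, or a `run_config` list.
#' @param out_dir Output directory for all products.
#' @return A `pritx_run` list: `units`, `abundance`, `dynamics`, `elements`,
#'   `motif_hits`, `candidates`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st_units <- stage_units(cfg, out_dir)
  dynamics <- stage_dynamics(cfg, out_dir)
  elements <- stage_elements(cfg, out_dir)
  motif_hits <- stage_motifs(cfg, out_dir)
  candidates <- stage_tfs(cfg, out_dir)
  summary <- list(
    units = list(n = nrow(st_units$units),
                 polycistronic = sum(st_units$units$polycistronic %||% logical(0))),
    dynamics = stats::setNames(as.list(dynamics$label), dynamics$unit_id),
    elements = as.list(table(elements$category)),
    motif_hits = list(total = nrow(motif_hits),
                      conserved = sum(motif_hits$conserved)),
    candidates = purrr::pmap(candidates[, c("rank", "tf", "log2fc")],
                             function(rank, tf, log2fc) {
                               list(rank = rank, tf = tf, log2fc = round(log2fc, 4))
                             })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(units = st_units$units, abundance = st_units$abundance,
                 dynamics = dynamics, elements = elements,
                 motif_hits = motif_hits, candidates = candidates,
                 summary = summary),
            class = "pritx_run")
}

#' @export
print.pritx_run <- function(x, ...) {
  cat(sprintf("<pritx_run> %d units (%s); %d elements; %d/%d conserved motif hits; %d candidate TFs\n",
              nrow(x$units),
              paste(sprintf("%s=%s", x$dynamics$unit_id, x$dynamics$label),
                    collapse = ", "),
              nrow(x$elements), sum(x$motif_hits$conserved), nrow(x$motif_hits),
              nrow(x$candidates)))
  invisible(x)
}
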