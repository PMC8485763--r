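## Top-level pipeline drivers: each reads validated input tables, runs one
## analysis stage end to end, and writes its outputs plus a JSON run
## manifest into `out_dir`.  Together with the simulator driver they allow
## full simulate -> analyze round trips from files alone.

#' Run the fluctuation-analysis stage on count and metadata files
#'
#' Fits the Luria--Delbrueck model per experiment label, writes a
#' rate table (`rate x 1e9` with 95% CI, mirroring the conventional
#' reporting scale) and a pairwise likelihood-ratio comparison table with
#' raw and Benjamini--Hochberg-adjusted p-values.
#'
#' @param counts_file per-culture counts (see [read_fluctuation_counts()]).
#' @param meta_file per-experiment metadata (see [read_experiment_meta()]).
#' @param out_dir output directory (created if needed).
#' @param max_count jackpot censoring threshold passed to [ld_fit()].
#' @return named list of `ld_fit` objects, invisibly.
#' @export
run_fluctuation <- function(counts_file, meta_file, out_dir,
                            max_count = 1000L) {
  counts <- read_fluctuation_counts(counts_file)
  meta <- read_experiment_meta(meta_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- setdiff(unique(counts$label), meta$label)
  if (length(missing))
    stop(sprintf("no metadata for experiment(s): %s",
                 paste(missing, collapse = ", ")))
  fits <- lapply(meta$label, function(lb) {
    cc <- counts$count[counts$label == lb]
    if (!length(cc)) stop(sprintf("no counts for experiment '%s'", lb))
    ld_fit(cc, epsilon = meta$epsilon[meta$label == lb],
           Nt = meta$Nt[meta$label == lb], label = lb,
           max_count = max_count)
  })
  names(fits) <- meta$label
  est <- do.call(rbind, lapply(fits, function(f)
    data.frame(label = f$label, n_cultures = length(f$counts),
               m = f$m, rate_1e9 = f$rate * 1e9,
               ci_low_1e9 = f$ci_rate[1] * 1e9,
               ci_high_1e9 = f$ci_rate[2] * 1e9,
               stringsAsFactors = FALSE)))
  write_tsv(est, file.path(out_dir, "rates.tsv"))
  if (length(fits) >= 2L) {
    pairs <- utils::combn(names(fits), 2L)
    lrt <- apply(pairs, 2L, function(pr) {
      ht <- ld_lrt(fits[[pr[1L]]], fits[[pr[2L]]])
      data.frame(label1 = pr[1L], label2 = pr[2L],
                 statistic = unname(ht$statistic), p = ht$p.value,
                 stringsAsFactors = FALSE)
    })
    lrt <- do.call(rbind, lrt)
    lrt$p_bh <- bh_adjust(lrt$p)
    write_tsv(lrt, file.path(out_dir, "lrt.tsv"))
  }
  write_run_manifest(file.path(out_dir, "manifest.json"), "fluctuation",
                     inputs = list(counts = counts_file, meta = meta_file),
                     params = list(max_count = max_count))
  invisible(fits)
}

#' Run the gel-quantification stage on a lane-profile file
#'
#' @param profiles_file long-format lane profiles
#'   (see [read_lane_profiles()]).
#' @param config_file YAML run configuration with keys `marker_lanes`
#'   (lane names used as ladder), `ladder_sizes` (nucleotides), and
#'   optionally `sz_min`, `G`, `df`, `prominence`, `peak_positions`.
#' @param out_dir output directory.
#' @return the [ribo_quant()] object, invisibly.
#' @export
run_gelquant <- function(profiles_file, config_file, out_dir) {
  lanes <- read_lane_profiles(profiles_file)
  cfg <- yaml::read_yaml(config_file)
  for (key in c("marker_lanes", "ladder_sizes"))
    if (is.null(cfg[[key]]))
      stop(sprintf("%s: missing required key '%s'", config_file, key))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mk <- as.character(cfg$marker_lanes)
  if (!all(mk %in% names(lanes)))
    stop("marker lane(s) not present in the profile table")
  rq <- ribo_quant(
    lanes = lanes[setdiff(names(lanes), mk)],
    marker_lanes = lanes[mk],
    marker_sizes = as.numeric(cfg$ladder_sizes),
    sz_min = if (is.null(cfg$sz_min)) 500 else cfg$sz_min,
    G = if (is.null(cfg$G)) 9.28e6 else cfg$G,
    df = if (is.null(cfg$df)) 40 else cfg$df,
    peak_positions = cfg$peak_positions,
    prominence = if (is.null(cfg$prominence)) 0.05 else cfg$prominence)
  diag <- cbind(rq$lanes,
                calib_a = rq$calibration$a, calib_b = rq$calibration$b,
                calib_r2 = rq$calibration$r2, sz_min = rq$sz_min)
  write_tsv(diag, file.path(out_dir, "lane_diagnostics.tsv"))
  mut <- rq$lanes[rq$lanes$rnhB != "wt" & !is.na(rq$lanes$n_ribo), ]
  if (nrow(mut)) {
    per_strain <- split(mut$n_ribo, mut$dnaE)
    wt_strain <- names(per_strain)[1L]
    if ("dnaE_wt" %in% names(per_strain)) wt_strain <- "dnaE_wt"
    summ <- summarize_ribo(per_strain, G = rq$G, reference = wt_strain)
    write_tsv(as.data.frame(summ), file.path(out_dir, "ribo_summary.tsv"))
  }
  write_run_manifest(file.path(out_dir, "manifest.json"), "gelquant",
                     inputs = list(profiles = profiles_file,
                                   config = config_file),
                     params = cfg)
  invisible(rq)
}

#' Run the mutation-spectrum stage
#'
#' Tabulates substitution calls (from a call table, or called from FASTA
#' reference + isolate sequences) inside the reporting window and writes
#' the class table plus a per-position long table for plotting.
#'
#' @param calls_file substitution-call table
#'   (see [read_substitution_calls()]); alternatively supply `ref_fasta`
#'   and `seqs_fasta`.
#' @param out_dir output directory.
#' @param ref_fasta,seqs_fasta FASTA paths (reference window; isolates).
#' @param offset gene coordinate of the first FASTA base.
#' @param window closed reporting window.
#' @param min_fraction hotspot threshold.
#' @return the [tabulate_spectrum()] object, invisibly.
#' @export
run_spectrum <- function(calls_file = NULL, out_dir,
                         ref_fasta = NULL, seqs_fasta = NULL,
                         offset = 1516L, window = c(1516L, 1717L),
                         min_fraction = 0.05) {
  if (is.null(calls_file)) {
    if (is.null(ref_fasta) || is.null(seqs_fasta))
      stop("supply `calls_file`, or both `ref_fasta` and `seqs_fasta`")
    ref <- read_isolate_fasta(ref_fasta)[[1L]]
    seqs <- read_isolate_fasta(seqs_fasta)
    calls <- do.call(rbind, lapply(names(seqs), function(id)
      call_substitutions(ref, seqs[[id]], offset = offset, isolate = id)))
  } else {
    calls <- read_substitution_calls(calls_file)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kept <- filter_window(calls, window[1L], window[2L])
  spec <- tabulate_spectrum(kept)
  cls <- data.frame(class = SUB_CLASSES,
                    count = unname(spec$counts[SUB_CLASSES]),
                    percent = round(unname(spec$percents[SUB_CLASSES]), 1),
                    stringsAsFactors = FALSE)
  cls <- rbind(cls,
               data.frame(class = c("transitions", "transversions", "total"),
                          count = c(spec$transitions, spec$transversions,
                                    spec$total),
                          percent = round(c(spec$percent_transitions,
                                            spec$percent_transversions, 100),
                                          1)))
  write_tsv(cls, file.path(out_dir, "spectrum.tsv"))
  write_tsv(spec$per_position, file.path(out_dir, "per_position.tsv"))
  hs <- find_hotspots(spec, min_fraction)
  write_tsv(data.frame(position = hs), file.path(out_dir, "hotspots.tsv"))
  write_run_manifest(file.path(out_dir, "manifest.json"), "spectrum",
                     inputs = list(calls = calls_file, ref = ref_fasta,
                                   seqs = seqs_fasta),
                     params = list(offset = offset, window = window,
                                   min_fraction = min_fraction))
  invisible(spec)
}

#' Generate a full synthetic data set on disk
#'
#' Writes drop-in input files for all three analysis stages: fluctuation
#' counts + metadata, gel lane profiles (wild-type and RNase HII-deficient
#' sample lanes plus ladder lanes) + YAML gel config, and a
#' substitution-call table, all derived from one [sim_config()] and seed.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @param n_isolates isolates for the substitution-call table.
#' @param ladder_sizes ladder fragment sizes rendered into marker lanes.
#' @param rho_wt nick density of the wild-type (RER-proficient) lanes;
#'   `cfg$rho` is used for the RNase HII-deficient lane.
#' @return invisible list of written file paths.
#' @export
run_simulate <- function(cfg, out_dir, seed = cfg$seed, n_isolates = 100L,
                         ladder_sizes = c(1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5),
                         rho_wt = cfg$rho / 2) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  counts <- simulate_fluctuation_counts(cfg, seed = seed)
  paths$counts <- file.path(out_dir, "fluctuation_counts.tsv")
  write_tsv(data.frame(label = "sim", count = counts), paths$counts)
  paths$meta <- file.path(out_dir, "fluctuation_meta.tsv")
  write_tsv(data.frame(label = "sim", epsilon = cfg$epsilon, Nt = cfg$Nt),
            paths$meta)

  lane_list <- list(
    list(label = "wt_1", rho = rho_wt, rnhB = "wt", dnaE = "dnaE_wt"),
    list(label = "wt_2", rho = rho_wt, rnhB = "wt", dnaE = "dnaE_wt"),
    list(label = "mut_1", rho = cfg$rho, rnhB = "drnhB", dnaE = "dnaE_mut"))
  prof <- list()
  for (i in seq_along(lane_list)) {
    ln <- lane_list[[i]]
    cfg_i <- cfg; cfg_i$rho <- ln$rho
    frags <- simulate_nicked_fragments(cfg_i, seed = seed + i)
    prof[[ln$label]] <- render_gel_lane(frags, cfg, label = ln$label,
                                        rnhB = ln$rnhB, dnaE = ln$dnaE,
                                        seed = seed + 100L + i)
  }
  for (k in 1:2) {
    lad <- paste0("ladder_", k)
    prof[[lad]] <- render_gel_lane(
      ladder_sizes, cfg, counts = round(max(ladder_sizes) / ladder_sizes),
      label = lad, seed = seed + 200L + k)
  }
  long <- do.call(rbind, lapply(prof, function(p)
    data.frame(lane = p$label, distance = p$distances,
               intensity = p$intensities, rnhB = p$rnhB, dnaE = p$dnaE,
               stringsAsFactors = FALSE)))
  paths$profiles <- file.path(out_dir, "lane_profiles.tsv")
  write_tsv(long, paths$profiles)
  paths$gel_config <- file.path(out_dir, "gel_config.yaml")
  yaml::write_yaml(list(marker_lanes = c("ladder_1", "ladder_2"),
                        ladder_sizes = ladder_sizes,
                        sz_min = 500, G = cfg$G),
                   paths$gel_config)

  calls <- simulate_substitution_calls(cfg, n_isolates, seed = seed + 300L)
  paths$calls <- file.path(out_dir, "substitution_calls.tsv")
  write_tsv(calls, paths$calls)

  paths$manifest <- file.path(out_dir, "manifest.json")
  write_run_manifest(paths$manifest, "simulate",
                     inputs = list(),
                     params = list(n_cultures = cfg$n_cultures,
                                   m_true = cfg$m_true,
                                   epsilon = cfg$epsilon, Nt = cfg$Nt,
                                   G = cfg$G, rho = cfg$rho,
                                   rho_wt = rho_wt,
                                   n_isolates = n_isolates),
                     seed = seed)
  invisible(paths)
}
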