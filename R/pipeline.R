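# End-to-end orchestration: simulate (or load) -> detect bouts ->
# preprocess -> classify -> correlate -> summarize, with one seed fanned
# out to named substreams and a manifest recording the configuration hash
# and per-stage counts.

#' Default analysis parameters
#'
#' Houses the pipeline constants: ~33 ms frame bins, 100 ms Gaussian
#' smoothing, 1000 shuffles, per-tail AUC alpha 0.025 (two-tailed 0.05),
#' two-sided correlation alpha 0.05, 10 s minimum circular shift, 20 mm
#' proximity threshold, and the PETH window.
#'
#' @param proximity_threshold proximity criterion (mm)
#' @param kernel_sigma Gaussian smoothing sigma (s)
#' @param n_shuffles shuffle/surrogate count
#' @param alpha_per_tail per-tail AUC significance criterion
#' @param corr_alpha two-sided correlation significance level
#' @param min_shift minimum circular shift (s)
#' @param min_duration,merge_gap bout post-processing (s)
#' @param offbout_pad off-bout mask dilation (s)
#' @param peth_window `c(pre, post)` seconds
#' @return named list of parameters
#' @export
analysis_params <- function(proximity_threshold = 20, kernel_sigma = 0.1,
                            n_shuffles = 1000, alpha_per_tail = 0.025,
                            corr_alpha = 0.05, min_shift = 10,
                            min_duration = 0.2, merge_gap = 0.5,
                            offbout_pad = 1, peth_window = c(2, 4)) {
  stopifnot(proximity_threshold > 0, kernel_sigma > 0, n_shuffles > 0,
            alpha_per_tail > 0, alpha_per_tail < 0.5,
            corr_alpha > 0, corr_alpha < 1, min_shift > 0)
  list(proximity_threshold = proximity_threshold,
       kernel_sigma = kernel_sigma, n_shuffles = n_shuffles,
       alpha_per_tail = alpha_per_tail, corr_alpha = corr_alpha,
       min_shift = min_shift, min_duration = min_duration,
       merge_gap = merge_gap, offbout_pad = offbout_pad,
       peth_window = peth_window)
}

#' Run the full analysis pipeline
#'
#' Synthetic mode simulates a joint session from `config$synth`; real-data
#' mode loads positions, spikes, and traces from `config$paths`. Stages:
#' bout detection, spike binning / smoothing / z-scoring, calcium
#' z-scoring, stream alignment, AUC modulation classification for both
#' regions, population summary, and pairwise correlation with surrogate
#' significance in full and off-bout epochs. All artifacts are written as
#' CSV/JSON under `out_dir` together with a manifest; identical config and
#' seed reproduce byte-identical outputs.
#'
#' @param config list (or YAML file path) with elements `mode`
#'   (`"synthetic"` or `"real"`), `seed`, optional `synth` (arguments to
#'   [synth_config()]), optional `analysis` (arguments to
#'   [analysis_params()]), and `paths` (positions/spikes/traces CSVs) in
#'   real mode
#' @param out_dir output directory (created if needed)
#' @return (invisibly) list with the run artifacts and the manifest
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode %||% "synthetic"
  seed <- as.integer(config$seed %||% 1L)
  params <- do.call(analysis_params, config$analysis %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (mode == "synthetic") {
    scfg <- do.call(synth_config, c(config$synth %||% list(), list(seed = seed)))
    session <- simulate_session(scfg)
    positions <- session$positions
    spikes <- session$spikes
    traces <- session$traces
    timeline <- session$timeline
  } else {
    for (p in c("positions", "spikes", "traces")) {
      if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]])) {
        abort(paste0("real-data mode: missing input file for '", p, "': ",
                     config$paths[[p]] %||% "<unset>"))
      }
    }
    positions <- read_positions_csv(config$paths$positions)
    spikes <- read_spikes_csv(config$paths$spikes)
    traces <- read_traces_csv(config$paths$traces)
    timeline <- positions %>% select("frame", "t")
    session <- NULL
  }
  n_frames <- nrow(timeline)

  # --- behavior ---
  flags <- detect_interaction_frames(positions, params$proximity_threshold)
  bouts <- assemble_bouts(flags, min_duration = params$min_duration,
                          merge_gap = params$merge_gap)
  ind <- bout_indicator(bouts, n_frames)
  write_bouts_csv(bouts, file.path(out_dir, "bouts.csv"))

  # --- preprocess ---
  ss <- if ("unit_class" %in% names(spikes)) {
    filter(spikes, .data$unit_class != "PC_CS")
  } else spikes
  rates <- bin_spikes(ss, timeline) %>%
    smooth_rate(sigma = params$kernel_sigma) %>%
    zscore_activity()
  traces_z <- zscore_activity(traces)
  al <- align_streams(rates, traces_z)

  # --- modulation ---
  mod_cb <- classify_modulation(
    al$rates, ind[al$frames + 1L], n_shuffles = params$n_shuffles,
    alpha = params$alpha_per_tail, min_shift = params$min_shift,
    seed = substream_seed(seed, "classify-cb"))
  mod_acc <- classify_modulation(
    al$traces, ind[al$frames + 1L], n_shuffles = params$n_shuffles,
    alpha = params$alpha_per_tail, min_shift = params$min_shift,
    seed = substream_seed(seed, "classify-acc"))
  readr::write_csv(as_tibble(mod_cb), file.path(out_dir, "modulation_cb.csv"))
  readr::write_csv(as_tibble(mod_acc), file.path(out_dir, "modulation_acc.csv"))
  pop <- population_summary(bind_rows(
    mutate(as_tibble(mod_cb), context = "cb_social"),
    mutate(as_tibble(mod_acc), context = "acc_social")))

  # --- correlation, full and off-bout ---
  cb_lab <- select(as_tibble(mod_cb), "unit_id", "label")
  acc_lab <- tibble(neuron_id = mod_acc$unit_id, label = mod_acc$label)
  masks <- list(
    full = build_epoch_mask(bouts, timeline, "full"),
    offbout = build_epoch_mask(bouts, timeline, "offbout",
                               pad = params$offbout_pad))
  pairs <- purrr::imap(masks, function(mk, nm) {
    correlate_pairs(al$rates, al$traces, mask = mk,
                    cb_labels = cb_lab, acc_labels = acc_lab,
                    n_shuffles = params$n_shuffles,
                    corr_alpha = params$corr_alpha,
                    min_shift = params$min_shift,
                    seed = substream_seed(seed, paste0("corr-", nm)))
  })
  for (nm in names(pairs)) {
    readr::write_csv(as_tibble(pairs[[nm]]),
                     file.path(out_dir, paste0("pairs_", nm, ".csv")))
  }
  csum <- class_summary(bind_rows(as_tibble(pairs$full), as_tibble(pairs$offbout)))

  summary_json <- list(
    population = pop,
    class_matrices = csum$matrices)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "socroc",
    version = as.character(utils::packageVersion("socroc")),
    mode = mode, seed = seed,
    config_hash = config_hash(paste(deparse(config), collapse = "\n")),
    n_frames = n_frames,
    n_bouts = nrow(bouts),
    n_cb_units = dplyr::n_distinct(rates$unit_id),
    n_acc_neurons = dplyr::n_distinct(traces_z$neuron_id),
    n_pairs = nrow(pairs$full),
    n_degenerate_pairs = sum(!is.na(pairs$full$flag)),
    substreams = c("behavior", "spikes", "calcium", "classify-cb",
                   "classify-acc", "corr-full", "corr-offbout"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(session = session, bouts = bouts, rates = al$rates,
                 traces = al$traces, modulation_cb = mod_cb,
                 modulation_acc = mod_acc, population = pop,
                 pairs = pairs, class_summary = csum, manifest = manifest))
}

#' Render summary figures for a completed run
#'
#' Reads the CSV artifacts under `run_dir` and writes PNG panels:
#' modulation-label proportions, correlation CDFs per class with full and
#' off-bout epochs, and significant-pair matrices. Missing artifacts skip
#' their panel with a notice; regeneration is idempotent.
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @param fig_dir output directory for figures (default `run_dir`/figures)
#' @return tibble of written figure files
#' @export
render_report <- function(run_dir, fig_dir = file.path(run_dir, "figures")) {
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save_fig <- function(plot, name) {
    path <- file.path(fig_dir, name)
    ggplot2::ggsave(path, plot, width = 7, height = 5, dpi = 120)
    written <<- c(written, path)
  }

  mod_files <- file.path(run_dir, c("modulation_cb.csv", "modulation_acc.csv"))
  if (all(file.exists(mod_files))) {
    mods <- bind_rows(
      mutate(readr::read_csv(mod_files[1], show_col_types = FALSE),
             context = "cerebellum"),
      mutate(readr::read_csv(mod_files[2], show_col_types = FALSE),
             context = "ACC"))
    save_fig(plot_modulation_proportions(population_summary(mods)),
             "modulation_proportions.png")
  } else {
    message("render_report: modulation tables missing; panel skipped")
  }

  pair_files <- file.path(run_dir, c("pairs_full.csv", "pairs_offbout.csv"))
  have <- file.exists(pair_files)
  if (any(have)) {
    pairs <- bind_rows(purrr::map(pair_files[have],
                                  readr::read_csv, show_col_types = FALSE))
    if (all(c("cb_label", "acc_label") %in% names(pairs))) {
      cs <- class_summary(pairs)
      save_fig(plot_corr_cdf(cs), "correlation_cdf.png")
      save_fig(plot_sig_matrix(cs, "positive"), "sig_matrix_positive.png")
      save_fig(plot_sig_matrix(cs, "negative"), "sig_matrix_negative.png")
    }
  } else {
    message("render_report: pair tables missing; panels skipped")
  }
  tibble(file = written)
}
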