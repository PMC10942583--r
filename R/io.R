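# Plain-text readers/writers for the pipeline's tabular formats: position
# tracks, spike trains, bout tables (CSV), and trace matrices (wide CSV,
# neurons as columns).

#' Read / write a position-track CSV
#'
#' Columns: frame, t, then x/y per tracked point (subject nose/body, LED,
#' target nose/body/tail) and a logical `valid` mask.
#'
#' @param path file path
#' @return tibble of positions
#' @export
read_positions_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("positions file not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(out, c("frame", "t"), what = path)
  out
}

#' @rdname read_positions_csv
#' @param positions tibble to write
#' @export
write_positions_csv <- function(positions, path) {
  readr::write_csv(positions, path)
  invisible(path)
}

#' Read / write a spike-train CSV (unit_id, unit_class, t)
#'
#' @param path file path
#' @return tibble of spike times
#' @export
read_spikes_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("spikes file not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(out, c("unit_id", "t"), what = path)
  arrange(out, .data$unit_id, .data$t)
}

#' @rdname read_spikes_csv
#' @param spikes tibble to write
#' @export
write_spikes_csv <- function(spikes, path) {
  readr::write_csv(spikes, path)
  invisible(path)
}

#' Read / write a bout table CSV (onset_s, offset_s, tag)
#'
#' @param path file path
#' @param frame_rate frame clock used to reconstruct frame indices
#' @return `bout_set` tibble
#' @export
read_bouts_csv <- function(path, frame_rate = 30) {
  if (!file.exists(path)) abort(paste0("bouts file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, c("onset_s", "offset_s"), what = path)
  out <- tibble(
    bout = seq_len(nrow(df)),
    onset_frame = as.integer(round(df$onset_s * frame_rate)),
    offset_frame = as.integer(round(df$offset_s * frame_rate)),
    onset_t = df$onset_s, offset_t = df$offset_s,
    n_frames = as.integer(round((df$offset_s - df$onset_s) * frame_rate)),
    tag = if ("tag" %in% names(df)) df$tag else NA_character_)
  structure(out, class = c("bout_set", class(out)))
}

#' @rdname read_bouts_csv
#' @param bouts `bout_set` tibble to write
#' @export
write_bouts_csv <- function(bouts, path) {
  readr::write_csv(
    tibble(onset_s = bouts$onset_t, offset_s = bouts$offset_t,
           tag = bouts$tag), path)
  invisible(path)
}

#' Read / write a trace matrix as wide CSV (frame, t, one column per neuron)
#'
#' @param path file path
#' @return long tibble (neuron_id, frame, t, value)
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("traces file not found: ", path))
  wide <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(wide, c("frame", "t"), what = path)
  wide %>%
    tidyr::pivot_longer(-c("frame", "t"), names_to = "neuron_id",
                        values_to = "value") %>%
    arrange(.data$neuron_id, .data$frame)
}

#' @rdname read_traces_csv
#' @param traces long tibble (neuron_id, frame, t, value) to write
#' @export
write_traces_csv <- function(traces, path) {
  check_cols(traces, c("neuron_id", "frame", "t", "value"))
  wide <- traces %>%
    tidyr::pivot_wider(id_cols = c("frame", "t"), names_from = "neuron_id",
                       values_from = "value") %>%
    arrange(.data$frame)
  readr::write_csv(wide, path)
  invisible(path)
}
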