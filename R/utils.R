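# Internal helpers: seeded substreams, small hashing, validation.

#' Derive a deterministic substream seed from a master seed and a label
#'
#' One master seed fans out into named substreams (behavior / spikes /
#' calcium / shuffles ...) so that each stage can be regenerated
#' independently without perturbing the others. Kept below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param name substream label
#' @return an integer seed
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 5381
  for (ch in utf8ToInt(name)) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# Evaluate expr under a named substream of `seed`, restoring RNG state after.
with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}

# Stable polynomial hash of a character vector, hex string. Fingerprints
# configurations in run manifests; not cryptographic.
config_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261 %% 2147483629
  for (b in bytes) h <- ((h + b) * 16777619) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# Frame interval of a timeline tibble (frame, t).
timeline_dt <- function(timeline) {
  stopifnot(all(c("frame", "t") %in% names(timeline)))
  dt <- diff(timeline$t)
  if (any(dt <= 0)) abort("timeline timestamps must be strictly increasing")
  stats::median(dt)
}

#' Build a session timeline
#'
#' @param n_frames number of frames
#' @param frame_rate nominal frame rate (Hz), ~30 for miniscope imaging
#' @param t0 time of the first frame (s)
#' @return tibble with columns `frame` (0-based) and `t` (s)
#' @export
make_timeline <- function(n_frames, frame_rate = 30, t0 = 0) {
  stopifnot(n_frames >= 1, frame_rate > 0)
  tibble(frame = 0:(n_frames - 1L), t = t0 + (0:(n_frames - 1L)) / frame_rate)
}

# circ_delay(a, b)[s + 1] = sum_i a[i] * b[((i - 1 - s) %% L) + 1],
# i.e. the masked product sum with b circularly delayed by s frames,
# computed for every s at once via the FFT cross-correlation identity.
circ_delay <- function(a, b) {
  L <- length(a)
  stopifnot(length(b) == L)
  Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / L
}

# Guard: x must be a data frame containing the given columns.
check_cols <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(x)
}
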