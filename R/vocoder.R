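#' Greenwood cochlear frequency-place map
#'
#' The map F(x) = A * (10^(a * x) - k) between basilar-membrane place x (mm,
#' measured from the apex) and characteristic frequency (Hz). Defaults are
#' the canonical human constants at a 35 mm cochlear length.
#'
#' @param A Frequency scale constant in Hz (default 165.4).
#' @param a Exponent constant per mm (default 0.06, i.e. 2.1 / 35 mm).
#' @param k Dimensionless integration constant in [0, 1) (default 0.88).
#' @param length_mm Cochlear length in mm (default 35).
#' @return A `greenwood_map` object.
#' @export
greenwood_map <- function(A = 165.4, a = 0.06, k = 0.88, length_mm = 35) {
  stopifnot(A > 0, a > 0, k >= 0, k < 1, length_mm > 0)
  structure(list(A = A, a = a, k = k, length_mm = length_mm),
            class = "greenwood_map")
}

#' @rdname greenwood_map
#' @param place_mm Place along the basilar membrane in mm.
#' @param map A [greenwood_map()].
#' @return `greenwood_freq()`: the characteristic frequency in Hz.
#' @export
greenwood_freq <- function(place_mm, map = greenwood_map()) {
  map$A * (10^(map$a * place_mm) - map$k)
}

#' @rdname greenwood_map
#' @param freq_hz Frequency in Hz; must exceed the map's minimum
#'   representable frequency `A * (1 - k)` at place 0... frequencies at or
#'   below `-A * k` have no place and raise an error.
#' @return `greenwood_place()`: place in mm (closed-form inverse).
#' @export
greenwood_place <- function(freq_hz, map = greenwood_map()) {
  arg <- freq_hz / map$A + map$k
  if (any(freq_hz <= 0) || any(arg <= 0))
    stop("frequency below the minimum representable value of the map",
         call. = FALSE)
  log10(arg) / map$a
}

#' Noise-band vocoder configuration
#'
#' @param n_channels Number of analysis/carrier channels (default 8).
#' @param lo_hz,hi_hz Overall analysis range (defaults 150 and 10000 Hz).
#' @param filter_order Total bandpass order; realized as cascaded
#'   Butterworth high-/low-pass sections of `filter_order / 2` each
#'   (default 6, i.e. 24 dB/octave band-edge skirts).
#' @param env_cutoff_hz Envelope low-pass cutoff (default 300 Hz).
#' @param env_order Envelope low-pass Butterworth order (default 4).
#' @return A `vocoder_config` object.
#' @export
vocoder_config <- function(n_channels = 8L, lo_hz = 150, hi_hz = 10000,
                           filter_order = 6L, env_cutoff_hz = 300,
                           env_order = 4L) {
  stopifnot(n_channels >= 1, lo_hz > 0, lo_hz < hi_hz, env_cutoff_hz > 0,
            filter_order >= 2, filter_order %% 2 == 0)
  structure(list(n_channels = as.integer(n_channels), lo_hz = lo_hz,
                 hi_hz = hi_hz, filter_order = as.integer(filter_order),
                 env_cutoff_hz = env_cutoff_hz,
                 env_order = as.integer(env_order)),
            class = "vocoder_config")
}

#' Greenwood-spaced filterbank band edges
#'
#' Maps the analysis range to cochlear place, divides the place span into
#' `n_channels` equal-length segments, and maps the boundaries back to
#' frequency. Unrounded edges are used for processing; rounded edges are
#' reported.
#'
#' @param config A [vocoder_config()].
#' @param map A [greenwood_map()].
#' @return A `band_edges` object: `hz` (unrounded, length `n_channels + 1`,
#'   strictly increasing from `lo_hz` to `hi_hz`) and `hz_rounded`.
#' @examples
#' band_edges()$hz_rounded  # 150 314 570 967 1586 2549 4046 6376 10000
#' @export
band_edges <- function(config = vocoder_config(), map = greenwood_map()) {
  places <- seq(greenwood_place(config$lo_hz, map),
                greenwood_place(config$hi_hz, map),
                length.out = config$n_channels + 1L)
  hz <- greenwood_freq(places, map)
  hz[1] <- config$lo_hz
  hz[length(hz)] <- config$hi_hz
  structure(list(hz = hz, hz_rounded = round(hz)), class = "band_edges")
}

#' @export
print.band_edges <- function(x, ...) {
  cat("Greenwood filterbank corner frequencies (Hz):\n")
  print(x$hz_rounded)
  invisible(x)
}

#' Extract a band's temporal envelope
#'
#' Half-wave rectification followed by causal Butterworth low-pass
#' filtering at `config$env_cutoff_hz`.
#'
#' @param band_signal A [waveform()] (one analysis band).
#' @param config A [vocoder_config()].
#' @return A [waveform()] holding the (non-negative, clipped at 1) envelope.
#' @export
extract_envelope <- function(band_signal, config = vocoder_config()) {
  stopifnot(inherits(band_signal, "waveform"), length(band_signal$samples) > 0)
  rect <- pmax(band_signal$samples, 0)
  lp <- signal::butter(config$env_order,
                       config$env_cutoff_hz / (band_signal$rate_hz / 2),
                       type = "low")
  env <- as.numeric(signal::filter(lp, rect))
  waveform(pmin(pmax(env, 0), 1), band_signal$rate_hz)
}

#' Noise-band vocode a waveform
#'
#' Band-filters the input into Greenwood-spaced channels, extracts each
#' band's envelope (half-wave rectification + low-pass), modulates an
#' independently drawn band-filtered white-noise carrier per channel, scales
#' every channel so its output RMS matches the analysis-band input RMS, and
#' sums the channels. Deterministic given `seed`.
#'
#' @param input A [waveform()]; its rate must be at least `2 * hi_hz`.
#' @param config A [vocoder_config()].
#' @param map A [greenwood_map()].
#' @param seed Integer seed for the carrier noise draws.
#' @param keep_channels Also return the per-channel signals and RMS levels
#'   (as attributes `channels`, `rms_in`, `rms_out`)?
#' @return A [waveform()] of the same length and rate as the input.
#' @export
vocode <- function(input, config = vocoder_config(), map = greenwood_map(),
                   seed = 20131105L, keep_channels = FALSE) {
  stopifnot(inherits(input, "waveform"))
  if (input$rate_hz < 2 * config$hi_hz)
    stop(sprintf("sampling rate %g Hz too low for the %g Hz band edge",
                 input$rate_hz, config$hi_hz), call. = FALSE)
  edges <- band_edges(config, map)$hz
  n <- length(input$samples)
  carriers <- local_rng(seed, replicate(config$n_channels, stats::rnorm(n),
                                        simplify = FALSE))
  half <- config$filter_order %/% 2
  out <- numeric(n)
  rms_in <- rms_out <- numeric(config$n_channels)
  chans <- if (keep_channels)
    matrix(0, n, config$n_channels) else NULL
  for (ch in seq_len(config$n_channels)) {
    band <- butter_bandpass(input$samples, edges[ch], edges[ch + 1],
                            input$rate_hz, order_per_edge = half)
    in_rms <- sqrt(mean(band^2))
    rms_in[ch] <- in_rms
    if (in_rms < 1e-9) next
    env <- extract_envelope(waveform(pmax(pmin(band, 1), -1), input$rate_hz),
                            config)$samples
    carrier <- butter_bandpass(carriers[[ch]], edges[ch], edges[ch + 1],
                               input$rate_hz, order_per_edge = half)
    mod <- env * carrier
    mod_rms <- sqrt(mean(mod^2))
    if (mod_rms > 0) mod <- mod * in_rms / mod_rms
    rms_out[ch] <- sqrt(mean(mod^2))
    if (keep_channels) chans[, ch] <- mod
    out <- out + mod
  }
  pk <- max(abs(out))
  if (pk > 1) out <- out / pk # guard against summation overshoot
  res <- waveform(out, input$rate_hz)
  if (keep_channels) {
    attr(res, "channels") <- chans
    attr(res, "rms_in") <- rms_in
    attr(res, "rms_out") <- rms_out
  }
  res
}
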