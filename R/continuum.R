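#' Spectral-peak specification
#'
#' One spectral peak of a synthetic fricative: a band of noise parameterized
#' by its center frequency, bandwidth, and level relative to the second
#' (reference) peak.
#'
#' @param center_hz Center frequency in Hz (> 0).
#' @param bandwidth_hz Spectral bandwidth in Hz (> 0).
#' @param rel_amp_db Amplitude in dB relative to peak 2 (peak 2 itself is 0).
#' @return A `peak_spec` object (named list).
#' @export
peak_spec <- function(center_hz, bandwidth_hz, rel_amp_db = 0) {
  if (!is.numeric(center_hz) || length(center_hz) != 1L || center_hz <= 0)
    stop("`center_hz` must be a single positive number", call. = FALSE)
  if (!is.numeric(bandwidth_hz) || length(bandwidth_hz) != 1L || bandwidth_hz <= 0)
    stop("`bandwidth_hz` must be a single positive number", call. = FALSE)
  structure(list(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
                 rel_amp_db = rel_amp_db), class = "peak_spec")
}

#' Default continuum endpoint parameters
#'
#' The three-peak spectral description of the /sh/ (step 1) and /s/ (step 9)
#' endpoints of the fricative continuum: center frequencies 2932/6130/8100 Hz
#' vs 6300/8200/9700 Hz, bandwidths 1500/3500/2520 vs 2000/3500/4000 Hz, and
#' relative levels +5/3, 0, -5/3 dB vs -5, 0, +5 dB (relative amplitudes are
#' stored exactly; printed tables round them to two or one decimals).
#'
#' @return A list with elements `sh` and `s`, each a list of three
#'   [peak_spec()] objects (SP1, SP2, SP3).
#' @export
continuum_endpoints <- function() {
  list(
    sh = list(peak_spec(2932, 1500,  5 / 3),
              peak_spec(6130, 3500,  0),
              peak_spec(8100, 2520, -5 / 3)),
    s  = list(peak_spec(6300, 2000, -5),
              peak_spec(8200, 3500,  0),
              peak_spec(9700, 4000,  5))
  )
}

#' Interpolate a fricative continuum between two endpoint spectra
#'
#' Center frequencies and bandwidths are interpolated geometrically (equal
#' ratios on a log-frequency scale) between the /sh/ and /s/ endpoints;
#' relative amplitudes are interpolated linearly in dB. Step 1 and step
#' `n_steps` reproduce the endpoints exactly.
#'
#' @param endpoint_sh,endpoint_s Lists of three [peak_spec()] objects
#'   (SP1, SP2, SP3) for the /sh/ and /s/ endpoints.
#' @param n_steps Number of continuum steps (>= 2); default 9.
#' @param duration_ms,rise_ms,fall_ms Temporal parameters applied to every
#'   step: total noise duration and the linear rise/fall of the amplitude
#'   contour (defaults 180, 115, 18 ms).
#' @return A `continuum_table`: a long-format data frame with columns
#'   `step`, `peak`, `center_hz`, `bandwidth_hz`, `rel_amp_db` and temporal
#'   attributes `duration_ms`, `rise_ms`, `fall_ms`.
#' @examples
#' ct <- interpolate_continuum()
#' subset(ct, peak == 1 & step == 5)$center_hz  # 4297.86 -> prints as 4298
#' @export
interpolate_continuum <- function(endpoint_sh = continuum_endpoints()$sh,
                                  endpoint_s  = continuum_endpoints()$s,
                                  n_steps = 9L,
                                  duration_ms = 180, rise_ms = 115,
                                  fall_ms = 18) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2)
    stop("`n_steps` must be a single integer >= 2", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (length(endpoint_sh) != 3L || length(endpoint_s) != 3L)
    stop("endpoints must each supply three peaks (SP1, SP2, SP3)", call. = FALSE)
  stopifnot(rise_ms + fall_ms <= duration_ms)
  for (p in c(endpoint_sh, endpoint_s)) {
    if (!inherits(p, "peak_spec")) stop("endpoints must be peak_spec objects", call. = FALSE)
  }
  rows <- lapply(1:3, function(j) {
    a <- endpoint_sh[[j]]; b <- endpoint_s[[j]]
    data.frame(
      step = seq_len(n_steps),
      peak = j,
      center_hz    = exp(seq(log(a$center_hz), log(b$center_hz),
                             length.out = n_steps)),
      bandwidth_hz = exp(seq(log(a$bandwidth_hz), log(b$bandwidth_hz),
                             length.out = n_steps)),
      rel_amp_db   = seq(a$rel_amp_db, b$rel_amp_db, length.out = n_steps)
    )
  })
  ct <- do.call(rbind, rows)
  ct <- ct[order(ct$step, ct$peak), ]
  rownames(ct) <- NULL
  # exact endpoint fidelity (seq() already guarantees this, but pin it)
  for (j in 1:3) {
    ct$center_hz[ct$step == 1 & ct$peak == j] <- endpoint_sh[[j]]$center_hz
    ct$center_hz[ct$step == n_steps & ct$peak == j] <- endpoint_s[[j]]$center_hz
  }
  structure(ct, class = c("continuum_table", "data.frame"),
            duration_ms = duration_ms, rise_ms = rise_ms, fall_ms = fall_ms)
}

#' Extract one continuum step as a synthesis specification
#'
#' @param ct A `continuum_table` from [interpolate_continuum()].
#' @param step Step index (1 = /sh/ endpoint).
#' @return A `fricative_step`: step index, three [peak_spec()]s ordered
#'   SP1 < SP2 < SP3 in center frequency, and the temporal parameters.
#' @export
fricative_step <- function(ct, step) {
  stopifnot(inherits(ct, "continuum_table"))
  rows <- ct[ct$step == step, ]
  if (nrow(rows) != 3L) stop("step ", step, " not found in continuum table", call. = FALSE)
  peaks <- lapply(1:3, function(j) {
    r <- rows[rows$peak == j, ]
    peak_spec(r$center_hz, r$bandwidth_hz, r$rel_amp_db)
  })
  cf <- vapply(peaks, `[[`, numeric(1), "center_hz")
  if (is.unsorted(cf, strictly = TRUE))
    stop("peak center frequencies must satisfy SP1 < SP2 < SP3", call. = FALSE)
  structure(list(step_index = step, peaks = peaks,
                 duration_ms = attr(ct, "duration_ms"),
                 rise_ms = attr(ct, "rise_ms"),
                 fall_ms = attr(ct, "fall_ms")),
            class = "fricative_step")
}

#' Construct a waveform object
#'
#' @param samples Numeric vector in [-1, 1], all finite.
#' @param rate_hz Sampling rate in Hz.
#' @return A `waveform` object.
#' @export
waveform <- function(samples, rate_hz) {
  if (!all(is.finite(samples))) stop("waveform samples must all be finite", call. = FALSE)
  if (length(samples) && max(abs(samples)) > 1 + 1e-12)
    stop("waveform samples must lie in [-1, 1]", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.1f ms), peak %.3f>\n",
              length(x$samples), x$rate_hz,
              1000 * length(x$samples) / x$rate_hz,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

# linear rise / flat / linear fall amplitude contour, in samples
amplitude_contour <- function(n, rate_hz, rise_ms, fall_ms) {
  n_rise <- round(rise_ms / 1000 * rate_hz)
  n_fall <- round(fall_ms / 1000 * rate_hz)
  env <- rep(1, n)
  if (n_rise > 0) env[seq_len(min(n_rise, n))] <- seq(0, 1, length.out = min(n_rise, n))
  if (n_fall > 0 && n_fall < n) {
    idx <- (n - n_fall + 1):n
    env[idx] <- pmin(env[idx], seq(1, 0, length.out = n_fall))
  }
  env
}

# 6th-order Butterworth bandpass realized as cascaded 3rd-order HP + LP
# sections (stable where a direct narrow-band tf design is not)
butter_bandpass <- function(x, lo_hz, hi_hz, rate_hz, order_per_edge = 3L) {
  ny <- rate_hz / 2
  hp <- signal::butter(order_per_edge, lo_hz / ny, type = "high")
  lp <- signal::butter(order_per_edge, hi_hz / ny, type = "low")
  as.numeric(signal::filter(lp, signal::filter(hp, x)))
}

# Butterworth-magnitude band shape: power response with -3 dB points at
# center +/- bandwidth/2 and 6th-order (18 dB/oct) skirts
band_power_shape <- function(freq_hz, center_hz, bandwidth_hz, n_poles = 3L) {
  1 / (1 + ((freq_hz - center_hz) / (bandwidth_hz / 2))^(2 * n_poles))
}

# composite target power spectrum of a fricative step: the incoherent sum
# of its three peak bands, each weighted by its relative level (relative
# amplitudes set the peak spectral density re peak 2)
fricative_power_spectrum <- function(step, freq_hz) {
  p_tot <- 0
  for (p in step$peaks) {
    p_tot <- p_tot + 10^(p$rel_amp_db / 10) *
      band_power_shape(freq_hz, p$center_hz, p$bandwidth_hz)
  }
  p_tot
}

#' Synthesize one fricative continuum step
#'
#' Shapes white noise into three spectral peaks by spectral-domain
#' filtering: the target power spectrum is the sum of three Butterworth-
#' magnitude bands (the specified -3 dB bandwidth centered at each peak
#' frequency, 6th-order skirts) weighted so each peak's spectral density
#' sits at its specified level relative to peak 2. The result carries the
#' rise/flat/fall amplitude contour and is normalized to the requested
#' digital headroom.
#'
#' @param step A `fricative_step` from [fricative_step()].
#' @param rate_hz Sampling rate; must satisfy
#'   `rate_hz >= 2 * (SP3$center_hz + SP3$bandwidth_hz / 2)`.
#' @param seed Integer seed for the noise draw (synthesis is deterministic
#'   given the seed).
#' @param headroom_db Peak normalization target in dBFS (default -3).
#' @return A [waveform()] of duration `step$duration_ms`.
#' @export
synthesize_fricative <- function(step, rate_hz = 44100, seed = 20131105L,
                                 headroom_db = -3) {
  stopifnot(inherits(step, "fricative_step"))
  for (j in seq_along(step$peaks)) {
    p <- step$peaks[[j]]
    if (rate_hz < 2 * (p$center_hz + p$bandwidth_hz / 2))
      stop(sprintf(
        "sampling rate %g Hz violates Nyquist for peak %d (upper edge %.0f Hz)",
        rate_hz, j, p$center_hz + p$bandwidth_hz / 2), call. = FALSE)
  }
  n <- round(step$duration_ms / 1000 * rate_hz)
  noise <- local_rng(seed, stats::rnorm(n))
  # two-sided frequency axis matching the DFT bin layout
  freq <- (seq_len(n) - 1) * rate_hz / n
  freq[freq > rate_hz / 2] <- freq[freq > rate_hz / 2] - rate_hz
  gain <- sqrt(fricative_power_spectrum(step, abs(freq)))
  out <- Re(stats::fft(stats::fft(noise) * gain, inverse = TRUE)) / n
  out <- out * amplitude_contour(n, rate_hz, step$rise_ms, step$fall_ms)
  pk <- max(abs(out))
  if (pk > 0) out <- out * 10^(headroom_db / 20) / pk
  waveform(out, rate_hz)
}

# run expr with a private RNG stream; caller's RNG state is untouched
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# second-order resonator (formant) filter with a per-sample frequency track
resonator_track <- function(x, f_hz, bw_hz, rate_hz) {
  n <- length(x)
  if (length(f_hz) == 1L) f_hz <- rep(f_hz, n)
  r <- exp(-pi * bw_hz / rate_hz)
  theta <- 2 * pi * f_hz / rate_hz
  a1 <- 2 * r * cos(theta)
  a2 <- -r * r # scalar: bandwidth is constant along the track
  g <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r * r) # ~unit gain at f
  y <- numeric(n)
  y1 <- 0; y2 <- 0
  for (i in seq_len(n)) {
    y[i] <- g[i] * x[i] + a1[i] * y1 + a2 * y2
    y2 <- y1; y1 <- y[i]
  }
  y
}

# formant targets (Hz): steady-state values by vowel and talker gender
vowel_formants <- function(vowel, gender) {
  tab <- list(
    i = list(male = c(270, 2290, 3010), female = c(310, 2790, 3310)),
    u = list(male = c(300,  870, 2240), female = c(370,  950, 2670))
  )
  tab[[vowel]][[gender]]
}

#' Synthesize a vocalic context (stand-in for a natural recording)
#'
#' Source-filter synthesis: a glottal pulse train (gender-scaled F0) with a
#' low level of seeded aspiration noise, filtered through three cascaded
#' formant resonators. The first 50 ms carry a formant transition whose F2/F3
#' onsets are raised for /s/-appropriate transitions and lowered for
#' /sh/-appropriate ones. These stand-ins are parametric defaults and do not
#' model any particular talker's voice.
#'
#' @param vowel `"i"` or `"u"`.
#' @param talker_gender `"female"` or `"male"`.
#' @param transition_source `"s"` or `"sh"`: which fricative the initial
#'   formant transitions are appropriate for.
#' @param rate_hz Sampling rate (default 44100).
#' @param duration_ms Vowel duration (default 250 ms).
#' @param talker_id Optional talker label (default derived from gender).
#' @param seed Integer seed (deterministic output given the seed).
#' @return A `vowel_context`: the factor levels plus an `audio` [waveform()].
#' @export
synthesize_vowel <- function(vowel = c("i", "u"),
                             talker_gender = c("female", "male"),
                             transition_source = c("sh", "s"),
                             rate_hz = 44100, duration_ms = 250,
                             talker_id = NULL, seed = 20131105L) {
  vowel <- match.arg(vowel)
  talker_gender <- match.arg(talker_gender)
  transition_source <- match.arg(transition_source)
  if (is.null(talker_id))
    talker_id <- paste0(toupper(substr(talker_gender, 1, 1)), "1")
  n <- round(duration_ms / 1000 * rate_hz)
  f0 <- if (talker_gender == "female") 210 else 120
  # glottal source: impulse train with -6 dB/oct tilt + faint aspiration
  src <- numeric(n)
  src[seq(1, n, by = round(rate_hz / f0))] <- 1
  src <- as.numeric(stats::filter(src, 0.98, method = "recursive"))
  src <- src + local_rng(seed, stats::rnorm(n, sd = 0.02))
  fmts <- vowel_formants(vowel, talker_gender)
  n_trans <- round(0.050 * rate_hz)
  onset_shift <- if (transition_source == "s") c(0, 250, 400) else c(0, -250, -400)
  out <- src
  for (k in 1:3) {
    traj <- rep(fmts[k], n)
    if (n_trans > 1 && n_trans <= n)
      traj[seq_len(n_trans)] <- fmts[k] +
        onset_shift[k] * seq(1, 0, length.out = n_trans)
    out <- resonator_track(out, traj, bw_hz = 60 + 20 * k, rate_hz = rate_hz)
  }
  out <- out * amplitude_contour(n, rate_hz, rise_ms = 10, fall_ms = 40)
  out <- out * 10^(-3 / 20) / max(abs(out))
  structure(list(vowel = vowel, talker_id = talker_id,
                 talker_gender = talker_gender,
                 transition_source = transition_source,
                 f0_hz = f0, formants_hz = fmts,
                 audio = waveform(out, rate_hz)),
            class = "vowel_context")
}

#' Splice a fricative onto a vocalic context
#'
#' Concatenates fricative-then-vowel with a 5 ms equal-power crossfade at
#' the junction (fade-out of the fricative tail against fade-in of the vowel
#' onset; total duration is preserved to the sample).
#'
#' @param fricative A [waveform()] (the fricative noise).
#' @param context A `vowel_context` from [synthesize_vowel()].
#' @param step_index Continuum step recorded in the token metadata.
#' @param xfade_ms Crossfade duration (default 5 ms).
#' @return A `stimulus_token`: `audio` [waveform()] plus all factor levels.
#' @export
assemble_token <- function(fricative, context, step_index = NA_integer_,
                           xfade_ms = 5) {
  stopifnot(inherits(fricative, "waveform"), inherits(context, "vowel_context"))
  v <- context$audio
  if (fricative$rate_hz != v$rate_hz)
    stop(sprintf("sample-rate mismatch: fricative %g Hz vs vowel %g Hz",
                 fricative$rate_hz, v$rate_hz), call. = FALSE)
  nf <- length(fricative$samples); nv <- length(v$samples)
  nx <- min(round(xfade_ms / 1000 * fricative$rate_hz), nf, nv)
  f <- fricative$samples; w <- v$samples
  if (nx > 1) {
    th <- seq(0, pi / 2, length.out = nx)
    f[(nf - nx + 1):nf] <- f[(nf - nx + 1):nf] * cos(th)
    w[1:nx] <- w[1:nx] * sin(th)
  }
  audio <- waveform(pmax(pmin(c(f, w), 1), -1), fricative$rate_hz)
  structure(list(step_index = step_index,
                 talker_id = context$talker_id,
                 talker_gender = context$talker_gender,
                 vowel = context$vowel,
                 transition_source = context$transition_source,
                 audio = audio),
            class = "stimulus_token")
}

#' Factorial stimulus grid for the audio-only experiment
#'
#' Full crossing of 9 continuum steps x 4 talkers (2 female, 2 male) x
#' 2 vowels x 2 formant-transition types: 144 token descriptors.
#'
#' @return A data frame with one row per token: `token_id`, `step`,
#'   `talker_id`, `voice_gender`, `vowel`, `transition`.
#' @export
build_grid_exp1 <- function() {
  g <- expand.grid(step = 1:9,
                   talker_id = c("F1", "F2", "M1", "M2"),
                   vowel = c("i", "u"),
                   transition = c("sh", "s"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$voice_gender <- ifelse(substr(g$talker_id, 1, 1) == "F", "female", "male")
  g$token_id <- sprintf("step%d_%s_%s_%sTrans",
                        g$step, g$talker_id, g$vowel, g$transition)
  g[, c("token_id", "step", "talker_id", "voice_gender", "vowel", "transition")]
}

#' Factorial stimulus grid for the audio-visual experiment
#'
#' Full crossing of 2 faces x 2 voices x 9 continuum steps x 2 consonant
#' lip-rounding levels x 2 vowels: 144 dubbed-token descriptors. Only
#' /s/-transition vowel audio is used, and vowel audio always matches vowel
#' video (no /i/-audio with /u/-video pairings).
#'
#' @return A data frame with one row per token: `token_id`, `step`,
#'   `voice_gender`, `face_gender`, `vowel` (shared by audio and video),
#'   `lip_rounding`, `transition` (always `"s"`).
#' @export
build_grid_exp2 <- function() {
  g <- expand.grid(step = 1:9,
                   voice_gender = c("female", "male"),
                   face_gender = c("female", "male"),
                   lip_rounding = c("rounded", "unrounded"),
                   vowel = c("i", "u"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$transition <- "s"
  g$token_id <- sprintf("step%d_voice%s_face%s_%s_%s",
                        g$step, substr(g$voice_gender, 1, 1),
                        substr(g$face_gender, 1, 1), g$lip_rounding, g$vowel)
  g[, c("token_id", "step", "voice_gender", "face_gender",
        "vowel", "lip_rounding", "transition")]
}
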