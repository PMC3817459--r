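# reference (baseline) level for every context factor; the treatment dummy
# is 1 at the other level
.context_reference <- c(voice_gender = "female", vowel = "i",
                        transition = "sh", face_gender = "female",
                        lip_rounding = "rounded")

.context_alternative <- c(voice_gender = "male", vowel = "u",
                          transition = "s", face_gender = "male",
                          lip_rounding = "unrounded")

#' Generative parameters of the categorization model
#'
#' The simulated listener responds /s/ with probability
#' `plogis(b0 + u_subject + b_x * x + sum(beta * z))`, where `x` is the
#' centered log-Hz position of the fricative's first spectral peak
#' (`x = log(sp1_hz) - log(f_med)`), `z` are treatment (0/1) dummies for the
#' context factors, and `u_subject ~ N(0, sigma_u^2)` is a per-subject
#' random intercept.
#'
#' @param b0 Baseline logit intercept.
#' @param b_x Slope per unit centered log Hz (> 0: higher peaks sound more
#'   /s/-like).
#' @param beta Named numeric vector of context coefficients (logits), named
#'   by factor column (`voice_gender`, `vowel`, `transition`, `face_gender`,
#'   `lip_rounding`); each applies when the factor is at its non-reference
#'   level.
#' @param sigma_u SD of the per-subject random intercept (logits, >= 0).
#' @param f_med Centering frequency in Hz (default: the continuum's median
#'   first-peak frequency, the geometric mean of 2932 and 6300 Hz, ~4298 Hz).
#' @return A `generative_params` object.
#' @export
generative_params <- function(b0 = 0, b_x = 8, beta = numeric(0),
                              sigma_u = 0.5, f_med = sqrt(2932 * 6300)) {
  stopifnot(b_x > 0, sigma_u >= 0, f_med > 0)
  if (length(beta) && is.null(names(beta)))
    stop("`beta` must be a named vector (names are context factor columns)",
         call. = FALSE)
  bad <- setdiff(names(beta), names(.context_reference))
  if (length(bad))
    stop("unknown context factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(b0 = b0, b_x = b_x, beta = beta, sigma_u = sigma_u,
                 f_med = f_med), class = "generative_params")
}

#' Convert a target boundary shift in Hz to a logit coefficient
#'
#' With treatment coding z in {0, 1} and a baseline 50% boundary at
#' `f_base` Hz, the coefficient `-b_x * log((f_base + target_shift_hz) /
#' f_base)` moves the boundary to `f_base + target_shift_hz` when z = 1.
#' This inverts the Hz "common currency" conversion of fitted context
#' effects.
#'
#' @param target_shift_hz Desired boundary shift in Hz (may be negative).
#' @param b_x Fricative slope in logits per log Hz (> 0).
#' @param f_base Baseline boundary in Hz (> 0).
#' @return The context coefficient in logits.
#' @export
calibrate_coefficient <- function(target_shift_hz, b_x, f_base) {
  stopifnot(b_x > 0, f_base > 0)
  if (f_base + target_shift_hz <= 0)
    stop("shift would place the boundary at a non-positive frequency",
         call. = FALSE)
  -b_x * log((f_base + target_shift_hz) / f_base)
}

#' Generative boundary implied by a parameter set
#'
#' Analytic 50% crossover in Hz for a given context configuration:
#' `f_med * exp(-(b0 + sum(beta * z)) / b_x)` (random intercept at its
#' mean, 0).
#'
#' @param params A [generative_params()].
#' @param context Named character vector of factor levels; omitted factors
#'   sit at their reference level.
#' @return Boundary frequency in Hz.
#' @export
generative_boundary <- function(params, context = character(0)) {
  stopifnot(inherits(params, "generative_params"))
  eta0 <- params$b0
  for (f in names(params$beta)) {
    lev <- if (f %in% names(context)) context[[f]] else .context_reference[[f]]
    if (lev == .context_alternative[[f]]) eta0 <- eta0 + params$beta[[f]]
  }
  params$f_med * exp(-eta0 / params$b_x)
}

#' Default generative parameters for the audio-only experiment
#'
#' Context coefficients are calibrated so the implied boundary shifts are
#' `shifts_hz` (defaults 702, 282 and 242 Hz for voice gender, vowel and
#' formant transition: shifts toward /s/ for male voices, /u/ vowels and
#' /s/-transitions). The slope default `b_x = 8` gives endpoint-step
#' identification probabilities above 0.95 at baseline.
#'
#' @param shifts_hz Named numeric: target boundary shifts in Hz for
#'   `voice_gender`, `vowel`, `transition`.
#' @param b_x,b0,sigma_u,f_med Passed to [generative_params()].
#' @return A `generative_params` object.
#' @export
default_params_exp1 <- function(shifts_hz = c(voice_gender = 702,
                                              vowel = 282, transition = 242),
                                b_x = 8, b0 = 0, sigma_u = 0.5,
                                f_med = sqrt(2932 * 6300)) {
  f_base <- f_med * exp(-b0 / b_x)
  beta <- vapply(shifts_hz, function(d)
    calibrate_coefficient(-d, b_x, f_base), numeric(1))
  generative_params(b0 = b0, b_x = b_x, beta = beta, sigma_u = sigma_u,
                    f_med = f_med)
}

#' Trial design grid
#'
#' Expands a stimulus grid ([build_grid_exp1()] or [build_grid_exp2()])
#' across subjects and repetitions.
#'
#' @param experiment 1 (audio-only) or 2 (audio-visual).
#' @param subjects Number of simulated subjects (default 10).
#' @param reps Repetitions per stimulus (default 5).
#' @return A `design_grid` data frame: one row per trial.
#' @export
design_grid <- function(experiment = 1, subjects = 10L, reps = 5L) {
  stopifnot(subjects >= 1, reps >= 1, experiment %in% c(1, 2))
  g <- if (experiment == 1) build_grid_exp1() else build_grid_exp2()
  out <- g[rep(seq_len(nrow(g)), times = subjects * reps), ]
  out$subject <- sprintf("S%02d", rep(seq_len(subjects),
                                      each = nrow(g) * reps))
  out$rep <- rep(rep(seq_len(reps), each = nrow(g)), times = subjects)
  rownames(out) <- NULL
  structure(out, class = c("design_grid", "data.frame"),
            experiment = experiment, subjects = as.integer(subjects),
            reps = as.integer(reps))
}

#' Simulate four-alternative identification responses
#'
#' For each subject a random intercept `u ~ N(0, sigma_u^2)` is drawn; each
#' trial's /s/ probability is `plogis(b0 + u + b_x * x + sum(beta * z))` and
#' the binary fricative decision is a Bernoulli draw. The reported word
#' combines the fricative decision with the (veridically perceived) stimulus
#' vowel: see/she for /i/, sue/shoe for /u/.
#'
#' @param grid A [design_grid()].
#' @param params A [generative_params()].
#' @param seed Integer seed (output is deterministic given the seed).
#' @param sp1_hz Optional vector of first-peak frequencies by continuum
#'   step; defaults to the standard 9-step ladder.
#' @return A `trial_table` data frame: the grid columns plus `sp1_hz`, `x`
#'   (centered log Hz), `response_word` and `response_s` (0/1).
#' @export
simulate_trials <- function(grid, params = default_params_exp1(),
                            seed = 20131105L, sp1_hz = NULL) {
  stopifnot(inherits(grid, "data.frame"), inherits(params, "generative_params"))
  if (is.null(sp1_hz)) {
    ct <- interpolate_continuum()
    sp1_hz <- ct$center_hz[ct$peak == 1]
  }
  if (any(grid$step < 1 | grid$step > length(sp1_hz)))
    stop("grid step index outside the continuum", call. = FALSE)
  d <- as.data.frame(grid)
  d$sp1_hz <- sp1_hz[d$step]
  d$x <- log(d$sp1_hz) - log(params$f_med)
  eta <- params$b0 + params$b_x * d$x
  for (f in names(params$beta)) {
    if (!f %in% names(d))
      stop("generative factor `", f, "` is not a column of the grid",
           call. = FALSE)
    eta <- eta + params$beta[[f]] * (d[[f]] == .context_alternative[[f]])
  }
  subjects <- unique(d$subject)
  d <- local_rng(seed, {
    u <- stats::rnorm(length(subjects), 0, params$sigma_u)
    names(u) <- subjects
    p <- stats::plogis(eta + u[d$subject])
    d$response_s <- stats::rbinom(nrow(d), 1L, p)
    d
  })
  d$response_word <- ifelse(d$response_s == 1,
                            ifelse(d$vowel == "i", "see", "sue"),
                            ifelse(d$vowel == "i", "she", "shoe"))
  structure(d, class = c("trial_table", "data.frame"),
            f_med = params$f_med)
}
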