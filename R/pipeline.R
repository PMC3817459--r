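#' Pipeline run configuration
#'
#' Bundles the sub-configurations of a full synthesis-to-analysis run.
#' Stage seeds are split deterministically from `seed` by a fixed counter
#' scheme (`seed + 1` synthesis, `+ 2` vocoding, `+ 3` simulation), so a
#' single master seed pins the whole run.
#'
#' @param experiment 1 (audio-only) or 2 (audio-visual).
#' @param out_dir Directory for artifacts (created if needed); `NULL`
#'   disables audio rendering.
#' @param seed Master seed.
#' @param rate_hz Synthesis sampling rate.
#' @param subjects,reps Simulated listener count and repetitions per token.
#' @param vocode_audio Apply the noise vocoder to rendered tokens?
#' @param params A [generative_params()] for the listener simulation.
#' @param vocoder A [vocoder_config()].
#' @param greenwood A [greenwood_map()].
#' @param candidates Candidate model terms for [forward_select()].
#' @param delta_aic AIC improvement threshold for term retention.
#' @param render_audio Render token WAV files? (requires `out_dir`).
#' @return A `run_config` object.
#' @export
run_config <- function(experiment = 1, out_dir = NULL, seed = 20131105L,
                       rate_hz = 44100, subjects = 10L, reps = 5L,
                       vocode_audio = FALSE,
                       params = default_params_exp1(),
                       vocoder = vocoder_config(),
                       greenwood = greenwood_map(),
                       candidates = NULL, delta_aic = 2,
                       render_audio = !is.null(out_dir)) {
  stopifnot(experiment %in% c(1, 2), subjects >= 1, reps >= 1)
  if (is.null(candidates)) {
    candidates <- if (experiment == 1) {
      c("x", "voice_gender", "vowel", "transition",
        "x:voice_gender", "x:vowel", "x:transition",
        "voice_gender:vowel", "voice_gender:transition", "vowel:transition")
    } else {
      c("x", "voice_gender", "face_gender", "vowel", "lip_rounding",
        "x:voice_gender", "x:face_gender", "x:vowel", "x:lip_rounding",
        "voice_gender:face_gender", "voice_gender:vowel",
        "face_gender:vowel", "face_gender:lip_rounding",
        "vowel:lip_rounding")
    }
  }
  if (render_audio && is.null(out_dir))
    stop("`render_audio = TRUE` requires `out_dir`", call. = FALSE)
  structure(list(experiment = experiment, out_dir = out_dir,
                 seed = as.integer(seed), rate_hz = rate_hz,
                 subjects = as.integer(subjects), reps = as.integer(reps),
                 vocode_audio = isTRUE(vocode_audio), params = params,
                 vocoder = vocoder, greenwood = greenwood,
                 candidates = candidates, delta_aic = delta_aic,
                 render_audio = isTRUE(render_audio)),
            class = "run_config")
}

render_tokens <- function(config) {
  grid <- if (config$experiment == 1) build_grid_exp1() else build_grid_exp2()
  ct <- interpolate_continuum()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  synth_seed <- config$seed + 1L
  voc_seed <- config$seed + 2L
  fric_cache <- lapply(1:9, function(s)
    synthesize_fricative(fricative_step(ct, s), config$rate_hz,
                         seed = synth_seed + s))
  paths <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    gender <- if ("talker_id" %in% names(row) && !is.na(row$talker_id))
      row$voice_gender else row$voice_gender
    ctx <- synthesize_vowel(row$vowel, gender, row$transition,
                            rate_hz = config$rate_hz,
                            talker_id = if ("talker_id" %in% names(row))
                              row$talker_id else NULL,
                            seed = synth_seed + 100L + i)
    tok <- assemble_token(fric_cache[[row$step]], ctx, step_index = row$step)
    audio <- tok$audio
    if (config$vocode_audio)
      audio <- vocode(audio, config$vocoder, config$greenwood,
                      seed = voc_seed + i)
    paths[i] <- file.path(config$out_dir, paste0(row$token_id, ".wav"))
    write_wav(audio, paths[i])
  }
  grid$path <- paths
  grid$md5 <- unname(tools::md5sum(paths))
  grid
}

#' Run the full synthesis-simulation-analysis pipeline
#'
#' Orchestrates stimulus-grid construction, optional audio rendering (and
#' vocoding), trial simulation, forward-selected mixed-logistic fitting,
#' and the Hz boundary-shift report. Any stage failure aborts with the
#' stage name; artifacts from completed stages are kept in the returned
#' (partial) result.
#'
#' @param config A [run_config()].
#' @return A list: `manifest` (token descriptors, with paths and checksums
#'   when audio was rendered), `trials`, `selection` (fit + trace), `fit`,
#'   `shifts`, and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  result <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  result$manifest <- stage("stimuli", {
    if (config$render_audio) render_tokens(config)
    else if (config$experiment == 1) build_grid_exp1() else build_grid_exp2()
  })
  result$trials <- stage("simulate", {
    grid <- design_grid(config$experiment, config$subjects, config$reps)
    simulate_trials(grid, config$params, seed = config$seed + 3L)
  })
  result$selection <- stage("fit", {
    forward_select(result$trials, config$candidates,
                   random_intercept = config$subjects > 1,
                   delta_threshold = config$delta_aic)
  })
  result$fit <- result$selection$fit
  result$shifts <- stage("report", {
    factors <- if (config$experiment == 1) {
      c("voice_gender", "vowel", "transition")
    } else {
      c("voice_gender", "face_gender", "vowel", "lip_rounding")
    }
    shift_table(result$fit, factors)
  })
  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(result$manifest,
                       file.path(config$out_dir, "manifest.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(result$trials),
                       file.path(config$out_dir, "trials.csv"),
                       row.names = FALSE)
      utils::write.csv(result$shifts,
                       file.path(config$out_dir, "shifts.csv"),
                       row.names = FALSE)
    })
  }
  result
}

#' Deterministic test fixtures
#'
#' Small objects used by the test suite: a 20-trial table containing both
#' response values, a 0.2 s noise waveform, and a toy 2-channel vocoder
#' configuration.
#'
#' @param seed Integer seed (default 20131105).
#' @param rate_hz Sampling rate of the fixture waveform.
#' @return A list: `trials20`, `wave`, `vocoder2`, `map`.
#' @export
make_fixtures <- function(seed = 20131105L, rate_hz = 24000) {
  grid <- design_grid(1, subjects = 2L, reps = 1L)
  params <- generative_params(b_x = 4, sigma_u = 0.3)
  trials <- simulate_trials(grid, params, seed = seed)
  sub <- trials[trials$step %in% c(1, 3, 5, 7, 9) &
                  trials$talker_id %in% c("F1", "M1") &
                  trials$transition == "sh", ]
  sub <- sub[seq_len(20), ]
  # a tiny table must still show both response categories
  if (length(unique(sub$response_s)) < 2) {
    sub$response_s[sub$step == 1][1] <- 0L
    sub$response_s[sub$step == 9][1] <- 1L
  }
  rownames(sub) <- NULL
  noise <- local_rng(seed, stats::rnorm(round(0.2 * rate_hz), sd = 0.2))
  list(trials20 = structure(sub,
                            class = c("trial_table", "data.frame"),
                            f_med = params$f_med),
       wave = waveform(pmax(pmin(noise, 1), -1), rate_hz),
       vocoder2 = vocoder_config(n_channels = 2L, lo_hz = 150, hi_hz = 8000),
       map = greenwood_map())
}
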