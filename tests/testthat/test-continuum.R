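test_that("continuum interpolation regenerates the printed parameter table", {
  ct <- interpolate_continuum()
  cell <- function(peak, step, col) ct[ct$peak == peak & ct$step == step, col]

  # spot cells, exact after rounding
  expect_equal(round(cell(1, 5, "center_hz")), 4298)
  expect_equal(round(cell(2, 5, "center_hz")), 7090)
  expect_equal(round(cell(2, 2, "center_hz")), 6357)
  expect_equal(round(cell(1, 5, "bandwidth_hz")), 1732)
  expect_equal(round(cell(1, 8, "rel_amp_db"), 2), -4.17)
  expect_equal(round(cell(3, 8, "rel_amp_db"), 1), 4.2)

  # full rows: printed values are exact log/linear interpolation up to the
  # source table's last-digit rounding (+/- 1 Hz)
  printed_sp1 <- c(2932, 3226, 3550, 3906, 4298, 4729, 5203, 5726, 6300)
  printed_sp2 <- c(6130, 6357, 6592, 6837, 7090, 7352, 7625, 7907, 8200)
  printed_bw1 <- c(1500, 1556, 1612, 1671, 1732, 1796, 1861, 1929, 2000)
  printed_bw3 <- c(2520, 2670, 2828, 2997, 3175, 3364, 3564, 3775, 4000)
  expect_true(all(abs(round(ct$center_hz[ct$peak == 1]) - printed_sp1) <= 1))
  expect_true(all(abs(round(ct$center_hz[ct$peak == 2]) - printed_sp2) <= 1))
  expect_true(all(abs(round(ct$bandwidth_hz[ct$peak == 1]) - printed_bw1) <= 1))
  expect_true(all(abs(round(ct$bandwidth_hz[ct$peak == 3]) - printed_bw3) <= 1))
  expect_equal(ct$bandwidth_hz[ct$peak == 2], rep(3500, 9))
  expect_equal(round(ct$rel_amp_db[ct$peak == 1], 2),
               c(1.67, 0.83, 0, -0.83, -1.67, -2.5, -3.33, -4.17, -5))
})

test_that("interpolation is geometric with exact endpoints and monotone peaks", {
  ep <- continuum_endpoints()
  ct <- interpolate_continuum(ep$sh, ep$s, n_steps = 9)
  for (j in 1:3) {
    f <- ct$center_hz[ct$peak == j]
    expect_identical(f[1], ep$sh[[j]]$center_hz)
    expect_identical(f[9], ep$s[[j]]$center_hz)
    ratios <- f[-1] / f[-9]
    expect_equal(ratios, rep(ratios[1], 8), tolerance = 1e-9)
    expect_true(all(diff(f) > 0))
    # middle step of an odd-length continuum is the geometric mean
    expect_equal(f[5], sqrt(f[1] * f[9]), tolerance = 1e-12)
  }
  # arbitrary endpoints, arbitrary length
  ct2 <- interpolate_continuum(
    list(peak_spec(1000, 200, 2), peak_spec(2000, 300, 0),
         peak_spec(3000, 400, -2)),
    list(peak_spec(1500, 250, -1), peak_spec(2500, 350, 0),
         peak_spec(4000, 500, 1)),
    n_steps = 5)
  expect_equal(ct2$center_hz[ct2$peak == 1 & ct2$step == 3],
               sqrt(1000 * 1500), tolerance = 1e-12)
  expect_error(interpolate_continuum(n_steps = 1), "n_steps")
  expect_error(peak_spec(-100, 200), "positive")
})

test_that("synthesized fricatives honor duration, contour and band levels", {
  ct <- interpolate_continuum()
  fs <- 44100
  w <- synthesize_fricative(fricative_step(ct, 5), fs, seed = 11)
  expect_equal(length(w$samples), round(0.180 * fs)) # 7938 samples
  expect_lte(max(abs(w$samples)), 1)
  expect_equal(max(abs(w$samples)), 10^(-3 / 20), tolerance = 1e-6)

  # amplitude contour: strongest short-window RMS lies at/after the 115 ms
  # rise, and the onset is much weaker than the plateau
  win <- round(0.005 * fs)
  n_win <- floor(length(w$samples) / win)
  wrms <- vapply(seq_len(n_win), function(i)
    rms(w$samples[((i - 1) * win + 1):(i * win)]), numeric(1))
  t_peak <- (which.max(wrms) - 0.5) * 0.005
  expect_gte(t_peak, 0.115 - 0.005)
  expect_lt(wrms[1], 0.2 * max(wrms))

  # spectral contract: measured density in each peak's band matches the
  # analytic composite spectrum (overlapping bands add in power) within
  # 1.5 dB (FFT oracle, narrow measurement windows, levels re peak 2)
  for (s in c(1, 5, 9)) {
    st <- fricative_step(ct, s)
    ws <- synthesize_fricative(st, fs, seed = 11)
    spec <- abs(stats::fft(ws$samples))^2
    nn <- length(spec) %/% 2
    fr <- (seq_len(nn) - 1) * fs / length(spec)
    meas <- exp_ <- numeric(3)
    for (j in 1:3) {
      p <- st$peaks[[j]]
      win <- fr >= p$center_hz - p$bandwidth_hz / 8 &
        fr <= p$center_hz + p$bandwidth_hz / 8
      meas[j] <- mean(spec[seq_len(nn)][win])
      exp_[j] <- mean(fricshift:::fricative_power_spectrum(st, fr[win]))
    }
    rel_meas <- 10 * log10(meas / meas[2])
    rel_exp <- 10 * log10(exp_ / exp_[2])
    expect_lt(max(abs(rel_meas - rel_exp)), 1.5,
              label = sprintf("band-level deviation at step %d", s))
  }

  # the morph tilts the spectrum: energy density near the /sh/ peak
  # (2932 Hz) falls and density near the top /s/ peak (9700 Hz) rises
  # monotonically from step 1 to step 9
  dens_at <- function(w, c0) {
    spec <- abs(stats::fft(w$samples))^2
    nn <- length(spec) %/% 2
    fr <- (seq_len(nn) - 1) * w$rate_hz / length(spec)
    mean(spec[seq_len(nn)][fr >= c0 - 200 & fr <= c0 + 200])
  }
  w159 <- lapply(c(1, 5, 9), function(s)
    synthesize_fricative(fricative_step(ct, s), fs, seed = 11))
  lo <- vapply(w159, dens_at, numeric(1), c0 = 2932)
  hi <- vapply(w159, dens_at, numeric(1), c0 = 9700)
  expect_true(all(diff(10 * log10(lo / hi)) < 0))

  # Nyquist violation names the offending peak
  expect_error(synthesize_fricative(fricative_step(ct, 9), 16000),
               "Nyquist.*peak")
  # determinism
  w2 <- synthesize_fricative(fricative_step(ct, 5), fs, seed = 11)
  expect_identical(w$samples, w2$samples)
})

test_that("vowel stand-ins follow gender and vowel acoustics deterministically", {
  vf <- synthesize_vowel("i", "female", "s", rate_hz = 24000)
  vm <- synthesize_vowel("i", "male", "s", rate_hz = 24000)
  expect_gt(vf$f0_hz, vm$f0_hz)
  vu <- synthesize_vowel("u", "female", "s", rate_hz = 24000)
  expect_lt(vu$formants_hz[2], vf$formants_hz[2])
  # F2 difference is audible in the spectrum, not just the metadata
  e_hi_i <- band_energy_fraction(vf$audio, 2200, 3200)
  e_hi_u <- band_energy_fraction(vu$audio, 2200, 3200)
  expect_gt(e_hi_i, e_hi_u)
  # determinism
  vf2 <- synthesize_vowel("i", "female", "s", rate_hz = 24000)
  expect_identical(vf$audio$samples, vf2$audio$samples)
  # transition source changes the onset but not the steady state
  vs <- synthesize_vowel("i", "female", "s", rate_hz = 24000)
  vsh <- synthesize_vowel("i", "female", "sh", rate_hz = 24000)
  n <- length(vs$audio$samples)
  onset <- seq_len(round(0.04 * 24000))
  late <- (n - round(0.05 * 24000)):n
  expect_false(isTRUE(all.equal(vs$audio$samples[onset],
                                vsh$audio$samples[onset])))
})

test_that("token assembly concatenates with crossfade and preserves duration", {
  fs <- 24000
  ct <- interpolate_continuum()
  fric <- synthesize_fricative(fricative_step(ct, 3), fs, seed = 2)
  ctx <- synthesize_vowel("u", "male", "s", rate_hz = fs)
  tok <- assemble_token(fric, ctx, step_index = 3)
  expect_equal(length(tok$audio$samples),
               length(fric$samples) + length(ctx$audio$samples))
  expect_lte(max(abs(tok$audio$samples)), 1)
  expect_identical(tok$vowel, "u")
  expect_identical(tok$transition_source, "s")
  expect_identical(tok$step_index, 3)

  # silence in, silence out
  sil <- waveform(numeric(fs %/% 10), fs)
  ctx_sil <- ctx
  ctx_sil$audio <- waveform(numeric(fs %/% 10), fs)
  expect_equal(max(abs(assemble_token(sil, ctx_sil)$audio$samples)), 0)

  # sample-rate mismatch is an error
  ctx44 <- synthesize_vowel("u", "male", "s", rate_hz = 44100)
  expect_error(assemble_token(fric, ctx44), "mismatch")
})

test_that("stimulus grids have the full factorial structure", {
  g1 <- build_grid_exp1()
  expect_equal(nrow(g1), 144)
  expect_equal(nrow(unique(g1)), 144)
  expect_equal(nrow(g1[g1$talker_id == "F1", ]), 36)
  expect_setequal(unique(g1$voice_gender), c("female", "male"))

  g2 <- build_grid_exp2()
  expect_equal(nrow(g2), 144)
  expect_equal(nrow(unique(g2)), 144)
  expect_true(all(g2$transition == "s"))
  # vowel audio and vowel video never conflict: one shared vowel column
  expect_true("vowel" %in% names(g2))
  expect_equal(nrow(unique(g2[, c("face_gender", "voice_gender")])), 4)
})
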