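# Stimulus synthesis: structure, harmonicity, energy matching, envelopes.

test_that("NCF default reproduces the published pulse-train structure", {
  w <- synthesize_ncf(seed = 1)
  expect_equal(length(w$samples), round(6 * w$sample_rate))
  seg <- segment_envelope(w, threshold_db = -40, min_gap = 0.05)
  expect_equal(nrow(seg), 5L)
  expect_true(all(abs((seg$end - seg$start) - 1) < 0.05))
  # pulses separated by 250 ms silences
  gaps <- seg$start[-1] - seg$end[-nrow(seg)]
  expect_true(all(abs(gaps - 0.25) < 0.05))
})

test_that("noise-free NCF has spectral peaks only at the three harmonics", {
  w <- synthesize_ncf(stimulus_spec("NCF", noise_level = 0))
  pk <- spectral_peaks(w)
  expect_equal(pk, c(500, 1000, 1500), tolerance = 1e-6)
  # lowest peak within one FFT bin of the fundamental
  bin <- w$sample_rate / length(w$samples)
  expect_lt(abs(min(pk) - 500), bin + 1e-9)
})

test_that("degenerate single-pulse NCF is a pure 3-harmonic tone", {
  sp <- stimulus_spec("NCF", n_pulses = 1, inter_pulse_silence = 0,
                      total_duration = 1, noise_level = 0)
  w <- synthesize_ncf(sp)
  expect_equal(length(w$samples), round(1 * w$sample_rate))
  expect_equal(spectral_peaks(w), c(500, 1000, 1500), tolerance = 1e-6)
})

test_that("NCF noise component stays confined to the 500-1500 Hz band", {
  sp_noise <- stimulus_spec("NCF", noise_level = 0.25)
  sp_clean <- stimulus_spec("NCF", noise_level = 0)
  wn <- synthesize_ncf(sp_noise, seed = 7)
  wc <- synthesize_ncf(sp_clean)
  # isolate the noise bed: both syntheses share the deterministic tonal
  # component up to a global scale, so project it out
  sc <- sum(wn$samples * wc$samples) / sum(wc$samples^2)
  noise <- wn$samples - sc * wc$samples
  spec <- Mod(stats::fft(noise))^2
  n <- length(noise)
  freqs <- (seq_len(n) - 1) * wn$sample_rate / n
  f2 <- pmin(freqs, wn$sample_rate - freqs)
  in_band <- f2 >= 500 & f2 <= 1500
  expect_gt(sum(spec[in_band]) / sum(spec), 0.95)
})

test_that("DFM default reproduces the published sweep-train structure", {
  w <- synthesize_dfm()
  expect_equal(length(w$samples), round(6 * w$sample_rate))
  seg <- segment_envelope(w, threshold_db = -40, min_gap = 0.05)
  expect_equal(nrow(seg), 6L)
  expect_true(all(abs((seg$end - seg$start) - 0.5) < 0.05))
})

test_that("DFM instantaneous frequency follows the analytic sweep law", {
  sp <- stimulus_spec("DFM")
  # harmonic 3 starts at 1500 Hz (the printed upper band edge) and the
  # fundamental ends at 50 Hz (the printed lower edge)
  expect_equal(instantaneous_frequency(sp, 0, harmonic = 3), 1500)
  expect_equal(instantaneous_frequency(sp, sp$pulse_duration, harmonic = 1), 50)
  # degenerate zero-span sweep is a constant-frequency tone
  flat <- stimulus_spec("DFM", fundamental_start = 100, fundamental_end = 100,
                        n_pulses = 1, inter_pulse_silence = 0,
                        total_duration = 0.5)
  expect_equal(instantaneous_frequency(flat, c(0, 0.25, 0.5)), rep(100, 3))
  w <- synthesize_dfm(flat)
  expect_equal(spectral_peaks(w, threshold = 0.3), c(100, 200, 300),
               tolerance = 1e-2)
})

test_that("upward sweeps are rejected", {
  expect_error(stimulus_spec("DFM", fundamental_start = 50,
                             fundamental_end = 500),
               "downward")
})

test_that("nyquist and duration bookkeeping violations are rejected", {
  expect_error(stimulus_spec("NCF", sample_rate = 2000), "Nyquist")
  expect_error(stimulus_spec("NCF", total_duration = 7), "bookkeeping")
})

test_that("duration bookkeeping holds across valid spec variants", {
  cases <- list(
    stimulus_spec("NCF"),
    stimulus_spec("DFM"),
    stimulus_spec("NCF", n_pulses = 3, pulse_duration = 0.4,
                  inter_pulse_silence = 0.1, total_duration = 1.4,
                  noise_level = 0),
    stimulus_spec("DFM", n_pulses = 2, pulse_duration = 0.25,
                  inter_pulse_silence = 0.75, total_duration = 2))
  for (sp in cases) {
    w <- if (sp$kind == "NCF") synthesize_ncf(sp, seed = 1) else synthesize_dfm(sp)
    expect_equal(length(w$samples), round(sp$total_duration * sp$sample_rate))
    expect_lte(max(abs(w$samples)), 1)
    expect_equal(rms(w), sp$target_rms, tolerance = 1e-12)
  }
})

test_that("match_rms equalizes energy exactly", {
  ncf <- synthesize_ncf(seed = 2)
  dfm <- synthesize_dfm()
  m <- match_rms(ncf, dfm)
  expect_identical(m$a$samples, ncf$samples)
  expect_equal(rms(m$a) / rms(m$b), 1, tolerance = 1e-9)
  # pure gain case
  half <- waveform(ncf$samples * 0.5, ncf$sample_rate)
  m2 <- match_rms(ncf, half)
  expect_equal(m2$b$samples, ncf$samples, tolerance = 1e-12)
  # identity
  m3 <- match_rms(ncf, ncf)
  expect_equal(m3$b$samples, ncf$samples)
  expect_error(match_rms(ncf, waveform(numeric(100), 44100)), "silent")
})

test_that("segment_envelope returns nothing for silence", {
  w <- waveform(numeric(44100), 44100)
  expect_equal(nrow(segment_envelope(w)), 0L)
})

test_that("spectrogram localizes tones and tracks the downward sweep", {
  sr <- 8000
  t <- (0:(sr - 1)) / sr
  tone <- waveform(0.5 * sin(2 * pi * 500 * t), sr)
  g <- spectrogram(tone, window = 0.05, overlap = 0.5)
  peak_f <- g$freq[apply(g$magnitude, 2, which.max)]
  bin <- g$freq[2] - g$freq[1]
  expect_true(all(abs(peak_f - 500) <= bin + 1e-9))

  sp <- stimulus_spec("DFM", n_harmonics = 1, n_pulses = 1,
                      inter_pulse_silence = 0, total_duration = 0.5,
                      sample_rate = 8000, ramp = 0)
  sw <- synthesize_dfm(sp)
  gs <- spectrogram(sw, window = 0.04, overlap = 0.75)
  bin_s <- gs$freq[2] - gs$freq[1]
  # fundamental argmax non-increasing through the sweep
  track <- gs$freq[apply(gs$magnitude, 2, which.max)]
  inner <- gs$time > 0.05 & gs$time < 0.45
  expect_true(all(diff(track[inner]) <= bin_s / 2 + 1e-9))
  # analytic trajectory agreement (within 3 bins; windowing smears ~1.5 bins)
  expect_true(all(abs(track[inner] -
                        instantaneous_frequency(sp, pmin(gs$time[inner] +
                                                           0.02, 0.5))) <=
                    3 * bin_s))

  z <- spectrogram(waveform(numeric(8000), 8000))
  expect_true(all(z$magnitude == 0))
  expect_error(spectrogram(tone, overlap = 1), "overlap")
  expect_error(spectrogram(tone, window = 1e-4), "window")
})

test_that("WAV and spec-JSON round-trips preserve the stimulus", {
  w <- synthesize_ncf(seed = 3)
  f <- tempfile(fileext = ".wav")
  write_wav(w, f)
  r <- read_wav(f)
  expect_equal(r$sample_rate, w$sample_rate)
  expect_lt(max(abs(r$samples - w$samples)), 2 / 32767)
  f32 <- tempfile(fileext = ".wav")
  write_wav(w, f32, bits = 32L)
  r32 <- read_wav(f32)
  expect_lt(max(abs(r32$samples - w$samples)), 1e-6)

  sp <- stimulus_spec("DFM", n_pulses = 2, total_duration = 2)
  js <- tempfile(fileext = ".json")
  write_stimulus_spec(sp, js)
  sp2 <- read_stimulus_spec(js)
  expect_equal(unclass(sp2), unclass(sp))
  unlink(c(f, f32, js))
})
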