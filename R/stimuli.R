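# Stimulus synthesis: the two complex sound cues of the Go/Go assay.
#
# NCF  — noise-embedded constant-frequency cue: a train of multiharmonic tone
#        pulses (fundamental 500 Hz, three harmonics) with band-limited noise
#        gated inside each pulse, separated by silences, 6 s total.
# DFM  — downward frequency-modulated cue: a train of multiharmonic downward
#        sweeps (fundamental gliding 500 -> 50 Hz per sweep), 6 s total.

#' Stimulus specification
#'
#' Builds a validated specification for one of the two Go/Go sound cues.
#' Defaults reproduce the published stimulus structure: the NCF cue is five
#' 1 s tonal pulses (500 Hz fundamental, three equal-amplitude harmonics,
#' narrowband noise confined to 500--1500 Hz) separated by 250 ms silences;
#' the DFM cue is six 500 ms downward sweeps (fundamental 500 -> 50 Hz,
#' three harmonics) each followed by a 500 ms silence. Both cues last 6 s.
#'
#' @param kind `"NCF"` or `"DFM"`.
#' @param fundamental_start,fundamental_end Fundamental frequency in Hz at
#'   pulse onset and offset. Equal for NCF; `fundamental_end <=
#'   fundamental_start` is required (downward sweeps only).
#' @param n_harmonics Number of equal-amplitude harmonics (>= 1).
#' @param pulse_duration Duration of one pulse/sweep in seconds.
#' @param n_pulses Number of pulses/sweeps.
#' @param inter_pulse_silence Silence between (or after) pulses, seconds.
#' @param total_duration Total stimulus duration in seconds; must be
#'   consistent with the pulse/silence bookkeeping within one sample.
#' @param noise_band Two-element numeric `c(low, high)` Hz for the gated
#'   noise bed, or `NULL` for none.
#' @param noise_level Noise RMS relative to the tonal component RMS within a
#'   pulse (linear amplitude ratio).
#' @param sample_rate Sampling rate in Hz.
#' @param target_rms Linear RMS amplitude the full synthesized waveform is
#'   scaled to (RMS taken over the whole duration, silences included).
#' @param ramp Raised-cosine on/off ramp per pulse, seconds.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("NCF", "DFM"),
                          fundamental_start = NULL,
                          fundamental_end = NULL,
                          n_harmonics = 3L,
                          pulse_duration = NULL,
                          n_pulses = NULL,
                          inter_pulse_silence = NULL,
                          total_duration = 6,
                          noise_band = NULL,
                          noise_level = NULL,
                          sample_rate = 44100,
                          target_rms = 0.1,
                          ramp = 0.005) {
  kind <- match.arg(kind)
  if (kind == "NCF") {
    if (is.null(fundamental_start)) fundamental_start <- 500
    if (is.null(fundamental_end)) fundamental_end <- fundamental_start
    if (is.null(pulse_duration)) pulse_duration <- 1.0
    if (is.null(n_pulses)) n_pulses <- 5L
    if (is.null(inter_pulse_silence)) inter_pulse_silence <- 0.25
    if (is.null(noise_band)) noise_band <- c(500, 1500)
    if (is.null(noise_level)) noise_level <- 0.25
  } else {
    if (is.null(fundamental_start)) fundamental_start <- 500
    if (is.null(fundamental_end)) fundamental_end <- 50
    if (is.null(pulse_duration)) pulse_duration <- 0.5
    if (is.null(n_pulses)) n_pulses <- 6L
    if (is.null(inter_pulse_silence)) inter_pulse_silence <- 0.5
    if (is.null(noise_level)) noise_level <- 0
  }
  spec <- structure(
    list(kind = kind,
         fundamental_start = fundamental_start,
         fundamental_end = fundamental_end,
         n_harmonics = as.integer(n_harmonics),
         pulse_duration = pulse_duration,
         n_pulses = as.integer(n_pulses),
         inter_pulse_silence = inter_pulse_silence,
         total_duration = total_duration,
         noise_band = noise_band,
         noise_level = noise_level,
         sample_rate = sample_rate,
         target_rms = target_rms,
         ramp = ramp),
    class = "stimulus_spec")
  validate_stimulus_spec(spec)
  spec
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec %s: %d x %.3g s pulses, F0 %g->%g Hz, %d harmonics, %g s total>\n",
              x$kind, x$n_pulses, x$pulse_duration, x$fundamental_start,
              x$fundamental_end, x$n_harmonics, x$total_duration))
  invisible(x)
}

# number of silence intervals implied by the bookkeeping
n_silences <- function(spec) {
  if (spec$inter_pulse_silence <= 0) return(0L)
  as.integer(round((spec$total_duration - spec$n_pulses * spec$pulse_duration) /
                     spec$inter_pulse_silence))
}

validate_stimulus_spec <- function(spec) {
  stopifnot(spec$n_harmonics >= 1L, spec$n_pulses >= 1L,
            spec$pulse_duration > 0, spec$sample_rate > 0,
            spec$total_duration > 0, spec$target_rms > 0)
  if (spec$fundamental_end > spec$fundamental_start)
    stop("fundamental_end must be <= fundamental_start (downward sweeps only)")
  nyq <- spec$sample_rate / 2
  fmax <- spec$n_harmonics * spec$fundamental_start
  if (fmax >= nyq)
    stop(sprintf("highest harmonic (%g Hz) is at or above Nyquist (%g Hz)", fmax, nyq))
  if (!is.null(spec$noise_band)) {
    if (length(spec$noise_band) != 2L || spec$noise_band[1] >= spec$noise_band[2])
      stop("noise_band must be c(low, high) with low < high")
    if (spec$noise_band[2] >= nyq)
      stop("noise_band upper edge at or above Nyquist")
  }
  ns <- n_silences(spec)
  # layout is pulse [silence] pulse ... with an optional trailing silence
  if (!ns %in% c(0L, spec$n_pulses - 1L, spec$n_pulses))
    stop(sprintf(
      "inconsistent duration bookkeeping: %d pulses admit %d or %d silences, got %d",
      spec$n_pulses, spec$n_pulses - 1L, spec$n_pulses, ns))
  built <- spec$n_pulses * spec$pulse_duration + ns * spec$inter_pulse_silence
  if (abs(built - spec$total_duration) > 1 / spec$sample_rate)
    stop(sprintf(
      "inconsistent duration bookkeeping: %d pulses x %g s + %d silences x %g s = %g s != %g s",
      spec$n_pulses, spec$pulse_duration, ns, spec$inter_pulse_silence,
      built, spec$total_duration))
  invisible(spec)
}

#' Sampled audio waveform
#'
#' @param samples Numeric vector of linear-amplitude samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-12)
    stop("waveform samples must lie in [-1, 1]")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, rms(x)))
  invisible(x)
}

#' Root-mean-square amplitude of a waveform
#' @param w A `waveform`.
#' @return Linear RMS amplitude.
#' @export
rms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  sqrt(mean(w$samples^2))
}

# evaluate RNG-dependent code under a private, restorable seed
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

raised_cosine_ramp <- function(n_pulse, n_ramp) {
  env <- rep(1, n_pulse)
  if (n_ramp > 0 && 2 * n_ramp <= n_pulse) {
    up <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    env[seq_len(n_ramp)] <- up
    env[n_pulse - n_ramp + seq_len(n_ramp)] <- rev(up)
  }
  env
}

# spectrally flat gaussian noise confined to [low, high] Hz, unit RMS
band_limited_noise <- function(n, sample_rate, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  # two-sided mask: keep bins whose aliased frequency falls in the band
  f2 <- pmin(freqs, sample_rate - freqs)
  keep <- f2 >= band[1] & f2 <= band[2]
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# one tonal pulse: equal-amplitude harmonics of a (possibly gliding) fundamental
synth_pulse <- function(spec) {
  sr <- spec$sample_rate
  n <- round(spec$pulse_duration * sr)
  t <- (seq_len(n) - 1) / sr
  f0 <- spec$fundamental_start
  f1 <- spec$fundamental_end
  # linear-in-frequency glide: phase(t) = 2*pi*(f0*t + (f1-f0)*t^2/(2*T))
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * spec$pulse_duration))
  tone <- rowSums(vapply(seq_len(spec$n_harmonics),
                         function(k) sin(k * phase), numeric(n)))
  tone <- tone / spec$n_harmonics
  if (!is.null(spec$noise_band) && spec$noise_level > 0) {
    nz <- band_limited_noise(n, sr, spec$noise_band)
    tone_rms <- sqrt(mean(tone^2))
    tone <- tone + nz * (spec$noise_level * tone_rms)
  }
  tone * raised_cosine_ramp(n, round(spec$ramp * sr))
}

synth_train <- function(spec, seed = NULL) {
  with_local_seed(seed, {
    sr <- spec$sample_rate
    n_total <- round(spec$total_duration * sr)
    out <- numeric(n_total)
    cell <- spec$pulse_duration + spec$inter_pulse_silence
    for (i in seq_len(spec$n_pulses) - 1L) {
      p <- synth_pulse(spec)
      i0 <- round(i * cell * sr)
      idx <- i0 + seq_along(p)
      idx <- idx[idx <= n_total]
      out[idx] <- out[idx] + p[seq_along(idx)]
    }
    cur <- sqrt(mean(out^2))
    out <- out * (spec$target_rms / cur)
    if (max(abs(out)) > 1)
      stop("target_rms too high: scaled waveform clips beyond [-1, 1]")
    waveform(out, sr)
  })
}

#' Synthesize the noise-embedded constant-frequency (NCF) cue
#'
#' A train of multiharmonic tone pulses with a band-limited noise bed gated
#' inside each pulse, separated by silences, with raised-cosine on/off ramps,
#' scaled to `spec$target_rms`.
#'
#' @param spec A `stimulus_spec` with `kind == "NCF"`.
#' @param seed Optional integer seed for the noise bed (the tonal component
#'   is deterministic).
#' @return A `waveform`.
#' @export
synthesize_ncf <- function(spec = stimulus_spec("NCF"), seed = NULL) {
  validate_stimulus_spec(spec)
  if (spec$kind != "NCF") stop("spec$kind must be 'NCF'")
  if (spec$fundamental_end != spec$fundamental_start)
    stop("NCF pulses are constant-frequency: fundamental_end must equal fundamental_start")
  synth_train(spec, seed)
}

#' Synthesize the downward frequency-modulated (DFM) cue
#'
#' A train of downward sweeps whose fundamental glides linearly from
#' `fundamental_start` to `fundamental_end` over each sweep, with
#' phase-coherent harmonics, silences and ramps as in [synthesize_ncf()].
#'
#' @inheritParams synthesize_ncf
#' @param spec A `stimulus_spec` with `kind == "DFM"`.
#' @return A `waveform`.
#' @export
synthesize_dfm <- function(spec = stimulus_spec("DFM"), seed = NULL) {
  validate_stimulus_spec(spec)
  if (spec$kind != "DFM") stop("spec$kind must be 'DFM'")
  synth_train(spec, seed)
}

#' Instantaneous frequency of a DFM sweep harmonic
#'
#' Analytic instantaneous frequency (the phase derivative over `2*pi`) of
#' harmonic `k` at time `t` within one sweep:
#' `k * (f0 + (f1 - f0) * t / T)`.
#'
#' @param spec A `stimulus_spec`.
#' @param t Time within the sweep, seconds (vectorized).
#' @param harmonic Harmonic index `k >= 1`.
#' @return Frequency in Hz.
#' @export
instantaneous_frequency <- function(spec, t, harmonic = 1L) {
  stopifnot(harmonic >= 1, all(t >= 0), all(t <= spec$pulse_duration))
  harmonic * (spec$fundamental_start +
                (spec$fundamental_end - spec$fundamental_start) * t / spec$pulse_duration)
}

#' Match the RMS amplitude of two waveforms
#'
#' Scales `b` so that its RMS equals the RMS of `a`; `a` is returned
#' unchanged. This is how the two cues are energy-matched.
#'
#' @param a,b `waveform` objects; both must be non-silent.
#' @return A list with elements `a` and `b`.
#' @export
match_rms <- function(a, b) {
  ra <- rms(a); rb <- rms(b)
  if (ra == 0 || rb == 0) stop("match_rms is undefined for silent waveforms")
  b$samples <- b$samples * (ra / rb)
  list(a = a, b = b)
}

#' Segment a waveform by its amplitude envelope
#'
#' Finds the maximal time intervals whose smoothed rectified envelope exceeds
#' a threshold relative to the envelope peak, merging intervals separated by
#' gaps shorter than `min_gap`. Used to verify the pulse/sweep structure of
#' synthesized cues.
#'
#' @param w A `waveform`.
#' @param threshold_db Threshold in dB relative to the envelope peak (< 0).
#' @param min_gap Gaps shorter than this (seconds) are bridged.
#' @param smooth Moving-average envelope smoother width, seconds.
#' @return A data.frame with columns `start` and `end` (seconds), sorted and
#'   non-overlapping; zero rows for silence.
#' @export
segment_envelope <- function(w, threshold_db = -40, min_gap = 0.05, smooth = 0.01) {
  stopifnot(inherits(w, "waveform"), threshold_db < 0)
  env <- abs(w$samples)
  k <- max(1L, round(smooth * w$sample_rate))
  if (k > 1L) {
    env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
    env[is.na(env)] <- 0
  }
  pk <- max(env)
  if (pk == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  above <- env > pk * 10^(threshold_db / 20)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  # merge across short gaps
  min_gap_n <- min_gap * w$sample_rate
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg[i, 1] - merged[nrow(merged), 2] < min_gap_n)
      merged[nrow(merged), 2] <- seg[i, 2]
    else merged <- rbind(merged, seg[i, ])
  }
  data.frame(start = (merged[, 1] - 1) / w$sample_rate,
             end = merged[, 2] / w$sample_rate)
}

#' Short-time Fourier magnitude spectrogram
#'
#' @param w A `waveform`.
#' @param window Analysis window length, seconds (must cover >= 8 samples).
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return A list of class `stft_grid` with `time` (s, column centers),
#'   `freq` (Hz) and `magnitude` (freq x time matrix).
#' @export
spectrogram <- function(w, window = 0.05, overlap = 0.5) {
  stopifnot(inherits(w, "waveform"))
  n_win <- round(window * w$sample_rate)
  if (n_win < 8) stop("window too short: needs >= 8 samples")
  if (overlap >= 1 || overlap < 0) stop("overlap must be in [0, 1)")
  sp <- signal::specgram(w$samples, n = n_win, Fs = w$sample_rate,
                         overlap = floor(overlap * n_win))
  structure(list(time = as.numeric(sp$t), freq = as.numeric(sp$f),
                 magnitude = abs(unname(sp$S))),
            class = "stft_grid")
}

#' Spectral peak frequencies of a waveform
#'
#' Local maxima of the full-length FFT magnitude spectrum above a relative
#' threshold; used to verify harmonic structure.
#'
#' @param w A `waveform`.
#' @param threshold Relative magnitude (fraction of the global peak) below
#'   which local maxima are ignored.
#' @param min_separation Peaks closer than this (Hz) to a stronger peak are
#'   treated as its sidelobes and suppressed. A pulse train's spectrum is a
#'   comb around each harmonic; this collapses each comb to its strongest
#'   line.
#' @return Numeric vector of peak frequencies (Hz), ascending.
#' @export
spectral_peaks <- function(w, threshold = 0.1, min_separation = 20) {
  n <- length(w$samples)
  mag <- Mod(stats::fft(w$samples))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * w$sample_rate / n
  is_peak <- c(FALSE, mag[2:(length(mag) - 1)] > mag[1:(length(mag) - 2)] &
                 mag[2:(length(mag) - 1)] > mag[3:length(mag)], FALSE)
  is_peak <- is_peak & mag > threshold * max(mag)
  pk <- which(is_peak)
  if (!length(pk)) return(numeric(0))
  keep <- logical(length(pk))
  o <- order(mag[pk], decreasing = TRUE)
  kept_freqs <- numeric(0)
  for (i in o) {
    f <- freqs[pk[i]]
    if (!length(kept_freqs) || all(abs(kept_freqs - f) >= min_separation)) {
      keep[i] <- TRUE
      kept_freqs <- c(kept_freqs, f)
    }
  }
  sort(freqs[pk[keep]])
}
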