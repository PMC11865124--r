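#' Specification of a synthetic complex tone
#'
#' Additive-synthesis recipe: `n_partials` harmonics of `f0_hz` (partial k at
#' frequency `k * f0`), relative amplitudes falling off at
#' `rolloff_db_per_octave` (-6 dB/octave gives amplitude proportional to
#' 1/k), random phase per partial, and a linear rise/sustain/decay amplitude
#' envelope whose segment lengths must sum to the duration.
#'
#' @param f0_hz fundamental frequency, Hz.
#' @param duration_ms total duration, ms.
#' @param n_partials number of harmonics (including the fundamental).
#' @param rolloff_db_per_octave spectral slope, dB per octave (negative).
#' @param rise_ms,sustain_ms,decay_ms envelope segments, ms.
#' @param sample_rate_hz sampling rate, Hz.
#' @return object of class `tone_spec`.
#' @export
tone_spec <- function(f0_hz, duration_ms = 200, n_partials = 4L,
                      rolloff_db_per_octave = -6, rise_ms = 5,
                      sustain_ms = 170, decay_ms = 25,
                      sample_rate_hz = 44100) {
  if (abs(rise_ms + sustain_ms + decay_ms - duration_ms) > 1e-9)
    stop("envelope segments must sum to the duration", call. = FALSE)
  if (f0_hz <= 0) stop("f0_hz must be positive", call. = FALSE)
  structure(list(f0_hz = f0_hz, duration_ms = duration_ms,
                 n_partials = as.integer(n_partials),
                 rolloff_db_per_octave = rolloff_db_per_octave,
                 rise_ms = rise_ms, sustain_ms = sustain_ms,
                 decay_ms = decay_ms, sample_rate_hz = sample_rate_hz),
            class = "tone_spec")
}

#' Synthesize a complex tone
#'
#' Sums the spec's partials with seeded random phases, applies the linear
#' envelope (zero amplitude at the first and last sample), and peak-
#' normalizes. Partials at or above the Nyquist frequency raise an error.
#'
#' @param spec a [tone_spec()].
#' @param seed integer seed for the per-partial phases.
#' @param peak peak amplitude after normalization (0 < peak <= 1).
#' @return numeric vector of samples in (-peak, peak).
#' @export
synthesize_tone <- function(spec, seed = 1L, peak = 0.9) {
  stopifnot(inherits(spec, "tone_spec"))
  rate <- spec$sample_rate_hz
  freqs <- spec$f0_hz * seq_len(spec$n_partials)
  if (any(freqs >= rate / 2))
    stop("partial above Nyquist frequency (", max(freqs), " Hz at rate ",
         rate, ")", call. = FALSE)
  n <- round_half_away(spec$duration_ms * rate / 1000)
  t_ms <- seq(0, spec$duration_ms, length.out = n)
  rng <- local_rng(seed)
  phases <- 2 * pi * vapply(seq_len(spec$n_partials),
                            function(k) rng$int(10000L) / 10000,
                            numeric(1))
  # amplitude of partial k: log2(k) octaves above f0. The rolloff uses the
  # 6 dB = factor 2 convention so that -6 dB/octave is amplitude exactly
  # proportional to 1/k.
  amps <- 2 ^ (spec$rolloff_db_per_octave * log2(seq_len(spec$n_partials)) / 6)
  wave <- numeric(n)
  for (k in seq_len(spec$n_partials))
    wave <- wave + amps[k] * sin(2 * pi * freqs[k] * t_ms / 1000 + phases[k])
  env <- tone_envelope(t_ms, spec$rise_ms, spec$sustain_ms, spec$decay_ms,
                       spec$duration_ms)
  wave <- wave * env
  m <- max(abs(wave))
  if (m > 0) wave <- wave * (peak / m)
  wave
}

tone_envelope <- function(t_ms, rise, sustain, decay, dur) {
  env <- rep(1, length(t_ms))
  if (rise > 0) {
    i <- t_ms < rise
    env[i] <- t_ms[i] / rise
  }
  if (decay > 0) {
    i <- t_ms > rise + sustain
    env[i] <- pmax(0, (dur - t_ms[i]) / decay)
  }
  env
}

#' Render the audio for one trial
#'
#' Five metronome ticks at the reference interval, a silent gap, then five
#' repetitions of the trial tone at the trial's IOI. Onset sample indices
#' are exact to the nearest sample; the loudness offset is applied to the
#' repeating tone as an exact scalar gain of `10^(db/20)`.
#'
#' @param tone a [tone_spec()] for the repeating tone.
#' @param ioi_ms trial interonset interval, ms.
#' @param metronome a [tone_spec()] for the tick (defaults to a 1 kHz,
#'   50 ms tick).
#' @param metronome_ioi_ms tick interval, ms.
#' @param gap_ms silence between the end of the last tick and the first tone
#'   onset, ms.
#' @param n_ticks,n_tones event counts.
#' @param loudness_db dB offset applied to the repeating tone.
#' @param seed phase seed passed to [synthesize_tone()].
#' @return list with `samples`, `sample_rate_hz`, `tick_onsets`,
#'   `tone_onsets` (0-based sample indices).
#' @export
render_trial_audio <- function(tone, ioi_ms, metronome = NULL,
                               metronome_ioi_ms = 550, gap_ms = 1800,
                               n_ticks = 5L, n_tones = 5L, loudness_db = 0,
                               seed = 1L) {
  stopifnot(inherits(tone, "tone_spec"))
  if (is.null(metronome))
    metronome <- tone_spec(1000, duration_ms = 50, rise_ms = 5,
                           sustain_ms = 25, decay_ms = 20,
                           sample_rate_hz = tone$sample_rate_hz)
  if (metronome$sample_rate_hz != tone$sample_rate_hz)
    stop("sample rates must match", call. = FALSE)
  rate <- tone$sample_rate_hz
  tick_wave <- synthesize_tone(metronome, seed = seed)
  tone_wave <- synthesize_tone(tone, seed = seed) * 10 ^ (loudness_db / 20)
  ms_to_sample <- function(ms) as.integer(round_half_away(ms * rate / 1000))
  tick_onsets <- ms_to_sample((seq_len(n_ticks) - 1) * metronome_ioi_ms)
  first_tone_ms <- (n_ticks - 1) * metronome_ioi_ms +
    metronome$duration_ms + gap_ms
  tone_onsets <- ms_to_sample(first_tone_ms + (seq_len(n_tones) - 1) * ioi_ms)
  total <- max(tone_onsets) + length(tone_wave)
  out <- numeric(total)
  for (s in tick_onsets) {
    i <- s + seq_along(tick_wave)
    out[i] <- out[i] + tick_wave
  }
  for (s in tone_onsets) {
    i <- s + seq_along(tone_wave)
    out[i] <- out[i] + tone_wave
  }
  list(samples = out, sample_rate_hz = rate,
       tick_onsets = tick_onsets, tone_onsets = tone_onsets)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF writer (no audio package is assumed). Samples are clipped to
#' the range -1..1 and quantized to 16-bit signed integers.
#'
#' @param samples numeric vector in the range -1..1.
#' @param path output file.
#' @param sample_rate_hz sampling rate.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz = 44100) {
  pcm <- as.integer(round_half_away(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")    # PCM, mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")   # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file written by [write_wav()]
#'
#' @param path input file.
#' @return list with `samples` (numeric, scaled back to -1..1) and
#'   `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  rate <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk", call. = FALSE)
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM supported", call. = FALSE)
      rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, raw(), size - 8)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate_hz = rate))
    } else {
      readBin(con, raw(), size)
    }
  }
}
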