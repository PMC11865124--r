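#' Log-spaced interonset interval grid
#'
#' Builds the tempo grid used in relative tempo judgment experiments: `n`
#' interonset intervals (IOIs) geometrically interpolated between the two
#' endpoints (inclusive), rounded to the nearest integer millisecond.
#' Tempos in beats per minute are computed from the rounded integer
#' intervals as `60000 / ioi` and reported to one decimal (the convention
#' that reproduces the published BPM table for this grid).
#'
#' @param max_ioi_ms slowest (largest) interval, ms.
#' @param min_ioi_ms fastest (smallest) interval, ms. Must not exceed
#'   `max_ioi_ms`; equal endpoints give a degenerate constant grid.
#' @param n number of intervals (>= 2, or any positive count when the
#'   endpoints are equal).
#' @param ref_ioi_ms metronome (reference) interval, ms.
#' @return An object of class `tempo_grid` with fields `iois_ms` (integer,
#'   strictly decreasing for a proper grid), `iois_unrounded`, `bpm` (1 dp),
#'   and `ref_ioi_ms`.
#' @examples
#' g <- log_spaced_iois(1000, 302, 15)
#' g$iois_ms[2]  # 918
#' g$iois_ms[8]  # 550, the metronome interval
#' @export
log_spaced_iois <- function(max_ioi_ms, min_ioi_ms, n = 15L, ref_ioi_ms = 550) {
  if (!is.numeric(max_ioi_ms) || !is.numeric(min_ioi_ms) ||
      max_ioi_ms <= 0 || min_ioi_ms <= 0)
    stop("IOI endpoints must be positive", call. = FALSE)
  if (min_ioi_ms > max_ioi_ms)
    stop("min_ioi_ms must not exceed max_ioi_ms", call. = FALSE)
  if (n < 2 && max_ioi_ms != min_ioi_ms)
    stop("n must be at least 2", call. = FALSE)
  raw <- exp(seq(log(max_ioi_ms), log(min_ioi_ms), length.out = n))
  iois <- round_half_away(raw)
  structure(
    list(iois_ms = iois,
         iois_unrounded = raw,
         bpm = round(60000 / iois, 1),
         ref_ioi_ms = ref_ioi_ms),
    class = "tempo_grid")
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.tempo_grid <- function(x, ...) {
  cat("Tempo grid:", length(x$iois_ms), "IOIs,",
      max(x$iois_ms), "to", min(x$iois_ms), "ms",
      "(ref", x$ref_ioi_ms, "ms)\n")
  print(data.frame(ioi_ms = x$iois_ms, bpm = x$bpm))
  invisible(x)
}

#' Convert an interonset interval to beats per minute
#'
#' @param ioi_ms interval in milliseconds (positive).
#' @return tempo in BPM, `60000 / ioi_ms` (unrounded).
#' @examples
#' round(ioi_to_bpm(550), 1)  # 109.1
#' @export
ioi_to_bpm <- function(ioi_ms) {
  if (!is.numeric(ioi_ms) || any(ioi_ms <= 0))
    stop("ioi_ms must be positive", call. = FALSE)
  60000 / ioi_ms
}

#' Fundamental frequency of a pitch in 12-tone equal temperament
#'
#' Accepts either a note label such as `"A4"`, `"D#5"` or `"Eb3"`, or an
#' integer number of semitones relative to A4. Frequencies are anchored at
#' A4 = 440 Hz: `f = 440 * 2^(semitones / 12)`.
#'
#' @param note note label (character) or semitone offset from A4 (numeric).
#' @return frequency in Hz.
#' @examples
#' pitch_frequency("A7")    # 3520
#' pitch_frequency("D#5")   # 622.25 (2 dp)
#' pitch_frequency(-24)     # A2 = 110
#' @export
pitch_frequency <- function(note) {
  if (is.numeric(note)) {
    semis <- note
  } else if (is.character(note)) {
    semis <- vapply(note, parse_note_label, numeric(1), USE.NAMES = FALSE)
  } else {
    stop("note must be a label or a semitone offset", call. = FALSE)
  }
  440 * 2 ^ (semis / 12)
}

# semitones from A4 for a label like "C#4"; octave numbering changes at C
parse_note_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", label))[[1]]
  if (length(m) == 0)
    stop("unparseable note label: ", label, call. = FALSE)
  base <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)[[toupper(m[2])]]
  acc <- switch(m[3], "#" = 1, "b" = -1, 0)
  octave <- as.integer(m[4])
  midi <- (octave + 1) * 12 + base + acc
  midi - 69  # A4 is MIDI note 69
}

#' Equal-temperament pitch ladder with integer codes
#'
#' A set of pitches with the consecutive integer codes used as the
#' polynomial predictor. For the standard octave ladder A2--A7 the codes are
#' the octave numbers 2--7; for any other equally spaced ladder codes start
#' wherever `first_code` says (inference on orthogonal contrasts is
#' invariant to affine recoding).
#'
#' @param labels note labels (see [pitch_frequency()]).
#' @param codes integer codes, one per label; defaults to consecutive
#'   integers starting at `first_code`.
#' @param first_code starting code when `codes` is not supplied.
#' @return object of class `pitch_set` with `labels`, `codes`, `f0_hz`.
#' @export
pitch_set <- function(labels, codes = NULL, first_code = 1L) {
  if (is.null(codes)) codes <- seq_along(labels) + first_code - 1L
  if (length(codes) != length(labels))
    stop("codes and labels must have equal length", call. = FALSE)
  if (any(diff(sort(codes)) != 1))
    stop("codes must be consecutive integers", call. = FALSE)
  structure(list(labels = labels, codes = as.integer(codes),
                 f0_hz = pitch_frequency(labels)),
            class = "pitch_set")
}

#' The six-octave ladder A2--A7 coded 2--7
#' @return a [pitch_set()].
#' @export
pitch_set_octaves <- function() {
  pitch_set(paste0("A", 2:7), codes = 2:7)
}

#' @export
print.pitch_set <- function(x, ...) {
  print(data.frame(label = x$labels, code = x$codes,
                   f0_hz = round(x$f0_hz, 2)))
  invisible(x)
}

#' Bin a tempo grid into equal-size tempo ranges
#'
#' Splits the grid into `n_bins` consecutive quintile-style groups from
#' slowest to fastest; bin 1 holds the largest IOIs.
#'
#' @param grid a [tempo_grid][log_spaced_iois()].
#' @param n_bins number of ranges; must divide the grid size.
#' @return integer vector of bin indices parallel to `grid$iois_ms`.
#' @export
tempo_range_bins <- function(grid, n_bins = 5L) {
  stopifnot(inherits(grid, "tempo_grid"))
  n <- length(grid$iois_ms)
  if (n %% n_bins != 0)
    stop("grid size ", n, " is not divisible by ", n_bins, " bins",
         call. = FALSE)
  rep(seq_len(n_bins), each = n %/% n_bins)
}

#' Constrained block randomization of trials
#'
#' Generates a full trial plan for one participant. Trials come in blocks of
#' one trial per pitch x tempo-range cell. Constraints:
#' \itemize{
#'   \item within each block every pitch appears exactly once per tempo
#'     range;
#'   \item consecutive trials within a block differ in both pitch and tempo
#'     range;
#'   \item across each group of `n_bins_per_range` (= 3) blocks, every pitch
#'     hears each tempo of each range exactly once and each loudness offset
#'     exactly once per pitch x range pair.
#' }
#' Ordering uses seeded rejection sampling (greedy placement with restart),
#' since a direct construction is not required; infeasibility after
#' `max_attempts` restarts raises an error.
#'
#' @param pitches a [pitch_set()].
#' @param grid a [tempo_grid][log_spaced_iois()].
#' @param n_blocks number of blocks; must be a multiple of the number of
#'   IOIs per range (3 for the standard grid).
#' @param loudness_db loudness offsets cycled across block groups.
#' @param seed integer randomization seed.
#' @param n_bins number of tempo ranges.
#' @param max_attempts restart bound for the ordering sampler.
#' @return data.frame of class `trial_plan` with columns `block`, `trial`,
#'   `pitch_label`, `pitch_code`, `f0_hz`, `ioi_ms`, `loudness_db`; the seed
#'   is kept in `attr(, "seed")`.
#' @export
randomize_trials <- function(pitches, grid, n_blocks = 3L,
                             loudness_db = c(-3, 0, 3), seed = 1L,
                             n_bins = 5L, max_attempts = 10000L) {
  stopifnot(inherits(pitches, "pitch_set"), inherits(grid, "tempo_grid"))
  bins <- tempo_range_bins(grid, n_bins)
  per_bin <- length(grid$iois_ms) %/% n_bins
  if (n_blocks %% per_bin != 0)
    stop("n_blocks must be a multiple of ", per_bin, call. = FALSE)
  if (length(loudness_db) != per_bin)
    stop("need one loudness level per IOI-per-range", call. = FALSE)
  n_pitch <- length(pitches$codes)
  rng <- local_rng(seed)

  blocks <- vector("list", n_blocks)
  n_groups <- n_blocks %/% per_bin
  for (grp in seq_len(n_groups)) {
    # per pitch x range: permute the range's IOIs and the loudness levels
    # independently across the blocks of this group
    ioi_of <- array(NA_real_, c(n_pitch, n_bins, per_bin))
    loud_of <- array(NA_real_, c(n_pitch, n_bins, per_bin))
    for (pi in seq_len(n_pitch)) {
      for (bi in seq_len(n_bins)) {
        iois <- grid$iois_ms[bins == bi]
        ioi_of[pi, bi, ] <- iois[rng$perm(per_bin)]
        loud_of[pi, bi, ] <- loudness_db[rng$perm(per_bin)]
      }
    }
    for (wb in seq_len(per_bin)) {
      b <- (grp - 1L) * per_bin + wb
      ord <- order_block(n_pitch, n_bins, rng, max_attempts)
      blocks[[b]] <- data.frame(
        block = b,
        pitch_idx = ord$pitch,
        bin = ord$bin,
        ioi_ms = ioi_of[cbind(ord$pitch, ord$bin, wb)],
        loudness_db = loud_of[cbind(ord$pitch, ord$bin, wb)])
    }
  }
  plan <- do.call(rbind, blocks)
  plan <- data.frame(
    block = plan$block,
    trial = seq_len(nrow(plan)),
    pitch_label = pitches$labels[plan$pitch_idx],
    pitch_code = pitches$codes[plan$pitch_idx],
    f0_hz = pitches$f0_hz[plan$pitch_idx],
    ioi_ms = plan$ioi_ms,
    loudness_db = plan$loudness_db,
    stringsAsFactors = FALSE)
  attr(plan, "seed") <- seed
  class(plan) <- c("trial_plan", "data.frame")
  plan
}

# order the pitch x bin cells of one block so consecutive cells differ in
# both pitch and bin; greedy with restart
order_block <- function(n_pitch, n_bins, rng, max_attempts) {
  cells <- expand.grid(pitch = seq_len(n_pitch), bin = seq_len(n_bins))
  n <- nrow(cells)
  for (attempt in seq_len(max_attempts)) {
    remaining <- seq_len(n)
    ord <- integer(n)
    ok <- TRUE
    prev_p <- prev_b <- 0L
    for (k in seq_len(n)) {
      cand <- remaining[cells$pitch[remaining] != prev_p &
                        cells$bin[remaining] != prev_b]
      if (length(cand) == 0) { ok <- FALSE; break }
      pick <- cand[rng$int(length(cand))]
      ord[k] <- pick
      remaining <- remaining[remaining != pick]
      prev_p <- cells$pitch[pick]
      prev_b <- cells$bin[pick]
    }
    if (ok) return(list(pitch = cells$pitch[ord], bin = cells$bin[ord]))
  }
  stop("trial ordering constraints infeasible after ", max_attempts,
       " attempts", call. = FALSE)
}

#' Check a trial plan against the randomization constraints
#'
#' Brute-force validator: scans every adjacent pair and tallies each block
#' and block group. Used as the independent check on [randomize_trials()].
#'
#' @param plan a [trial_plan][randomize_trials()].
#' @param grid the grid it was built from.
#' @param n_bins number of tempo ranges.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_trial_plan <- function(plan, grid, n_bins = 5L) {
  bins <- tempo_range_bins(grid, n_bins)
  bin_of <- function(ioi) bins[match(ioi, grid$iois_ms)]
  per_bin <- length(grid$iois_ms) %/% n_bins
  for (b in unique(plan$block)) {
    blk <- plan[plan$block == b, ]
    tab <- table(blk$pitch_code, bin_of(blk$ioi_ms))
    if (any(tab != 1))
      stop("block ", b, ": pitch x range cell count != 1", call. = FALSE)
    for (k in seq_len(nrow(blk) - 1)) {
      if (blk$pitch_code[k] == blk$pitch_code[k + 1])
        stop("block ", b, ": consecutive trials share a pitch", call. = FALSE)
      if (bin_of(blk$ioi_ms[k]) == bin_of(blk$ioi_ms[k + 1]))
        stop("block ", b, ": consecutive trials share a tempo range",
             call. = FALSE)
    }
  }
  n_groups <- length(unique(plan$block)) %/% per_bin
  for (grp in seq_len(n_groups)) {
    blks <- ((grp - 1L) * per_bin + 1L):(grp * per_bin)
    g <- plan[plan$block %in% blks, ]
    # every pitch x IOI pairing exactly once per group
    if (any(table(g$pitch_code, g$ioi_ms) != 1))
      stop("group ", grp, ": pitch x tempo pairing not unique", call. = FALSE)
    # each loudness once per pitch x range
    key <- paste(g$pitch_code, bin_of(g$ioi_ms))
    for (k in unique(key)) {
      if (any(table(g$loudness_db[key == k]) != 1))
        stop("group ", grp, ": loudness not balanced within pitch x range",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Self-contained RNG so plan generation never disturbs the global
# .Random.seed: a linear congruential generator is plenty for permutations.
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
  list(
    int = function(n) as.integer(floor(nxt() * n)) + 1L,
    perm = function(n) {
      out <- integer(n)
      pool <- seq_len(n)
      for (k in seq_len(n)) {
        i <- as.integer(floor(nxt() * length(pool))) + 1L
        out[k] <- pool[i]
        pool <- pool[-i]
      }
      out
    })
}
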