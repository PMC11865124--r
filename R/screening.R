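#' Flag participants who used the slider as a discrete scale
#'
#' A participant is a discrete responder when at least `threshold_count` of
#' their ratings land exactly on the anchor values (scale endpoints and
#' midpoint). The reference rule is 75 of 90 trials; for other trial counts
#' the threshold scales pro-rata as `ceiling(75/90 * n)` unless an explicit
#' count is given.
#'
#' @param ratings 0--100 slider ratings.
#' @param threshold_count explicit anchor count threshold, or `NULL` for the
#'   pro-rata rule.
#' @param anchor_values ratings treated as anchors.
#' @return logical flag.
#' @export
is_discrete_responder <- function(ratings, threshold_count = NULL,
                                  anchor_values = c(0, 50, 100)) {
  if (length(ratings) == 0)
    stop("empty rating list", call. = FALSE)
  if (any(ratings < 0 | ratings > 100))
    stop("ratings must lie in [0, 100]", call. = FALSE)
  if (is.null(threshold_count))
    threshold_count <- ceiling(75 / 90 * length(ratings))
  sum(ratings %in% anchor_values) >= threshold_count
}

#' Correlation between ratings and true relative tempo
#'
#' Pearson correlation between the ratings and the log2 relative tempo of
#' each trial, with relative tempo computed as `ref_ioi / ioi` (so faster
#' trials score higher). Constant ratings give an undefined correlation,
#' returned as `NA`.
#'
#' @param ratings 0--100 slider ratings.
#' @param iois_ms trial interonset intervals, ms.
#' @param ref_ioi_ms metronome interval, ms.
#' @return Pearson r, or `NA` when undefined.
#' @export
truth_correlation <- function(ratings, iois_ms, ref_ioi_ms = 550) {
  if (length(ratings) != length(iois_ms))
    stop("ratings and iois_ms must match in length", call. = FALSE)
  if (length(ratings) < 3)
    stop("need at least 3 trials", call. = FALSE)
  x <- log2(ref_ioi_ms / iois_ms)
  if (stats::sd(x) == 0)
    stop("tempo is constant across trials", call. = FALSE)
  if (stats::sd(ratings) == 0) return(NA_real_)
  stats::cor(ratings, x)
}

#' Apply participant-level exclusion rules
#'
#' Two rules, in priority order: (1) discrete responders
#' ([is_discrete_responder()]); (2) low or negative correlation
#' (r below `r_min`) between ratings and true relative tempo
#' ([truth_correlation()]). Participants with an undefined correlation
#' (constant ratings) are excluded under the low-correlation reason.
#' Screening is invariant to trial order.
#'
#' @param trials trial data.frame with columns `participant_id`, `rating`,
#'   `ioi_ms`.
#' @param ref_ioi_ms metronome interval, ms.
#' @param r_min minimum acceptable truth correlation.
#' @param apply_discrete whether the discrete-responder rule is active
#'   (it can be disabled for designs where only the correlation rule is
#'   stated).
#' @return data.frame of class `screening_report`: `participant_id`,
#'   `n_trials`, `n_anchor`, `r`, `excluded`, `reason`
#'   (`"none"`, `"discrete"`, `"low_correlation"`).
#' @export
screen_participants <- function(trials, ref_ioi_ms = 550, r_min = 0.5,
                                apply_discrete = TRUE) {
  stopifnot(all(c("participant_id", "rating", "ioi_ms") %in% names(trials)))
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    discrete <- apply_discrete && is_discrete_responder(tr$rating)
    r <- if (stats::sd(tr$rating) == 0) NA_real_
         else truth_correlation(tr$rating, tr$ioi_ms, ref_ioi_ms)
    reason <- if (discrete) "discrete"
              else if (is.na(r) || r < r_min) "low_correlation"
              else "none"
    data.frame(participant_id = id, n_trials = nrow(tr),
               n_anchor = sum(tr$rating %in% c(0, 50, 100)),
               r = r, excluded = reason != "none", reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screening_report", "data.frame")
  out
}
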