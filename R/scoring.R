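#' Ground-truth rating for a relative tempo
#'
#' The response scale's intended log-linear mapping: a rating of 50 marks a
#' stimulus tempo equal to the metronome's and every doubling of tempo adds
#' 50 rating points:
#' \deqn{r_{true} = 50 + 50 \log_2(t / t_{ref})}
#' Values are not clipped to the 0--100 slider range.
#'
#' @param t stimulus tempo (BPM, or any unit shared with `t_ref`).
#' @param t_ref metronome tempo in the same unit.
#' @return ground-truth rating (rating points).
#' @examples
#' ground_truth_rating(109.1, 109.1)  # 50
#' ground_truth_rating(120, 60)       # 100
#' @export
ground_truth_rating <- function(t, t_ref) {
  if (any(t <= 0) || any(t_ref <= 0))
    stop("tempos must be positive", call. = FALSE)
  50 + 50 * log2(t / t_ref)
}

#' Cook's distance for a simple linear regression
#'
#' Per-observation influence on the ordinary least squares fit of `y` on
#' `x` (with intercept):
#' \deqn{D_i = \frac{e_i^2}{p\,s^2} \cdot \frac{h_{ii}}{(1-h_{ii})^2}}
#' with p = 2 parameters, s^2 the residual mean square and h the leverage.
#' Observations with leverage 1 get `Inf` (infinite influence).
#'
#' @param x predictor.
#' @param y response.
#' @return numeric vector of distances.
#' @export
cooks_distance_ols <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  X <- cbind(1, x)
  p <- 2
  XtX <- crossprod(X)
  if (abs(det(XtX)) < 1e-12 * n^2)
    stop("rank-deficient design (single tempo?)", call. = FALSE)
  beta <- solve(XtX, crossprod(X, y))
  e <- y - X %*% beta
  h <- rowSums((X %*% solve(XtX)) * X)
  s2 <- sum(e^2) / (n - p)
  # an exact fit leaves only floating-point rubble in the residuals;
  # treat it as zero influence rather than dividing noise by noise
  if (s2 < 1e-20 * max(1, mean(y^2))) return(rep(0, n))
  d <- as.vector(e^2 / (p * s2) * h / (1 - h)^2)
  d[h >= 1 - 1e-12] <- Inf
  d
}

#' Calibrate a participant's response scale
#'
#' Fits the per-subject line rating ~ log2 relative tempo by ordinary least
#' squares, flags influential trials on the initial fit (Cook's distance
#' greater than `cooks_multiplier / n`, n the trial count), and refits once
#' with the flagged trials removed. The refit intercept `beta0` is the
#' expected rating at the metronome tempo; the slope `beta1` is rating
#' points per tempo doubling. The relative tempo of a trial is computed as
#' `ref_ioi / ioi` so no rounding through BPM occurs.
#'
#' @param ioi_ms trial interonset intervals, ms.
#' @param rating 0--100 slider ratings.
#' @param ref_ioi_ms metronome interval, ms.
#' @param cooks_multiplier numerator of the outlier threshold (default 4).
#' @return object of class `calibration`: `beta0`, `beta1`, `outlier`
#'   (logical per trial), `cooks_d`, `cooks_threshold`, `n_used`, `x`
#'   (log2 relative tempo), plus the inputs.
#' @export
fit_calibration <- function(ioi_ms, rating, ref_ioi_ms = 550,
                            cooks_multiplier = 4) {
  n <- length(ioi_ms)
  if (length(rating) != n)
    stop("ioi_ms and rating must match in length", call. = FALSE)
  if (n < 3) stop("need at least 3 trials", call. = FALSE)
  x <- log2(ref_ioi_ms / ioi_ms)
  if (length(unique(x)) < 2)
    stop("degenerate fit: single tempo", call. = FALSE)
  d <- cooks_distance_ols(x, rating)
  threshold <- cooks_multiplier / n
  outlier <- is.finite(d) & d > threshold | is.infinite(d)
  keep <- !outlier
  if (sum(keep) < 3 || length(unique(x[keep])) < 2)
    stop("degenerate fit after outlier exclusion", call. = FALSE)
  cf <- stats::lm.fit(cbind(1, x[keep]), rating[keep])$coefficients
  structure(list(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
                 outlier = outlier, cooks_d = d,
                 cooks_threshold = threshold, n_used = sum(keep),
                 x = x, rating = rating, ioi_ms = ioi_ms,
                 ref_ioi_ms = ref_ioi_ms),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration: beta0 = %.3f, beta1 = %.3f (%d of %d trials; %d outliers)\n",
    x$beta0, x$beta1, x$n_used, length(x$outlier), sum(x$outlier)))
  invisible(x)
}

#' Predicted rating under a calibration model
#' @param object a [calibration][fit_calibration()].
#' @param newdata optional list/data.frame with `ioi_ms`; defaults to the
#'   fitted trials.
#' @param ... unused.
#' @return predicted ratings.
#' @export
predict.calibration <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else log2(object$ref_ioi_ms / newdata$ioi_ms)
  object$beta0 + object$beta1 * x
}

#' Residual tempo rating
#'
#' Observed minus predicted rating (the calibration model removes the
#' subject's own scale use, so these average to zero over included trials).
#'
#' @param model a [calibration][fit_calibration()].
#' @return numeric vector, one residual per trial (outlier trials included
#'   in the vector but flagged in `model$outlier`).
#' @export
residual_rating <- function(model) {
  model$rating - predict(model)
}

#' Illusory tempo shift in log2-percent
#'
#' Converts residual ratings to percent-of-a-doubling shifts:
#' \deqn{\tau_i = 100 \cdot \rho_i / \beta_1}
#' 100% means the trial was rated as if its tempo had doubled.
#'
#' @param rho residual rating(s).
#' @param beta1 calibration slope (rating points per doubling); must be
#'   nonzero.
#' @return shift(s) in log2-percent.
#' @export
illusory_shift <- function(rho, beta1) {
  if (beta1 == 0) stop("undefined shift: beta1 = 0", call. = FALSE)
  100 * rho / beta1
}

#' Perceived tempo implied by a rating
#'
#' Inverts the calibration line:
#' \deqn{\hat t_i = t_{ref} \cdot 2^{(r_i - \beta_0)/\beta_1}}
#'
#' @param rating observed rating(s).
#' @param model a [calibration][fit_calibration()].
#' @param t_ref metronome tempo in BPM (defaults to the model's reference
#'   interval converted to BPM).
#' @return perceived tempo in the unit of `t_ref`.
#' @export
perceived_tempo <- function(rating, model, t_ref = NULL) {
  if (model$beta1 == 0) stop("undefined: beta1 = 0", call. = FALSE)
  if (is.null(t_ref)) t_ref <- 60000 / model$ref_ioi_ms
  t_ref * 2 ^ ((rating - model$beta0) / model$beta1)
}

#' Score a trial table: calibration, residuals, illusory shifts
#'
#' Runs the full per-subject scoring pipeline on (screened) trial data:
#' fits each participant's calibration with single-pass Cook's-distance
#' outlier exclusion, then computes residual ratings and illusory shifts
#' from the refit model. Outlier trials are flagged and must be excluded
#' from all downstream analyses; their rho/tau values are reported for
#' audit but carry `is_outlier = TRUE`.
#'
#' @param trials trial data.frame with columns `participant_id`, `ioi_ms`,
#'   `rating` (other columns pass through).
#' @param ref_ioi_ms metronome interval, ms.
#' @param cooks_multiplier outlier threshold numerator.
#' @return list with `shifts` (the trial table plus `is_outlier`, `rho`,
#'   `tau`, `perceived_bpm`) and `models` (named list of calibrations).
#' @export
score_shifts <- function(trials, ref_ioi_ms = 550, cooks_multiplier = 4) {
  stopifnot(all(c("participant_id", "ioi_ms", "rating") %in% names(trials)))
  ids <- unique(trials$participant_id)
  models <- vector("list", length(ids))
  names(models) <- as.character(ids)
  pieces <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[i], , drop = FALSE]
    m <- fit_calibration(tr$ioi_ms, tr$rating, ref_ioi_ms, cooks_multiplier)
    rho <- residual_rating(m)
    tr$is_outlier <- m$outlier
    tr$rho <- rho
    tr$tau <- illusory_shift(rho, m$beta1)
    tr$perceived_bpm <- perceived_tempo(tr$rating, m)
    models[[i]] <- m
    pieces[[i]] <- tr
  }
  list(shifts = do.call(rbind, pieces), models = models)
}

#' Per-subject calibration coefficient table
#'
#' @param models the `models` element of [score_shifts()].
#' @return data.frame with `participant_id`, `beta0`, `beta1`, `n_used`,
#'   `n_outliers`.
#' @export
calibration_table <- function(models) {
  data.frame(
    participant_id = names(models),
    beta0 = vapply(models, `[[`, numeric(1), "beta0"),
    beta1 = vapply(models, `[[`, numeric(1), "beta1"),
    n_used = vapply(models, `[[`, numeric(1), "n_used"),
    n_outliers = vapply(models, function(m) sum(m$outlier), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
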