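#' True pitch-bias curve for the simulator
#'
#' Defines the per-pitch illusory shift (log2-percent) injected into
#' simulated ratings. Either supply explicit `values` (one per code; they
#' are centered to sum to zero, since shifts are defined relative to each
#' subject's own mean), or compose the curve from the orthogonal basis as
#' `linear * P1 + quadratic * P2` -- the default is the inverted-U shape
#' with a small positive linear tilt (+0.5 on P1) and a dominant negative
#' quadratic (-2.0 on P2) at unit basis scale.
#'
#' @param codes pitch codes.
#' @param linear,quadratic coefficients on the unit-norm orthogonal basis.
#' @param values optional explicit per-code shifts (overrides the basis
#'   composition).
#' @return object of class `bias_curve`: `codes`, `values` (centered).
#' @export
pitch_bias_curve <- function(codes = 2:7, linear = 0.5, quadratic = -2,
                             values = NULL) {
  codes <- sort(unique(as.numeric(codes)))
  if (is.null(values)) {
    b <- ortho_basis(codes, degree = 2)
    values <- as.vector(b$P %*% c(linear, quadratic))
  } else {
    if (length(values) != length(codes))
      stop("one value per code required", call. = FALSE)
    values <- values - mean(values)
  }
  structure(list(codes = codes, values = values), class = "bias_curve")
}

curve_at <- function(curve, codes) {
  curve$values[match(codes, curve$codes)]
}

#' Simulation configuration
#'
#' The stated world of the generator: a study-shaped design, per-subject
#' response-scale idiosyncrasies around the ground-truth line (intercept
#' mean 50, slope mean 50), trial-level rating noise, an injected
#' pitch-bias curve, a tap manipulation with a failure probability, and a
#' mix of responder types for exercising the screening rules.
#'
#' @param n_subjects number of simulated participants.
#' @param pitches a [pitch_set()].
#' @param grid a [tempo_grid][log_spaced_iois()].
#' @param n_blocks blocks per participant (3 gives the 90-trial shape,
#'   6 the 180-trial shape).
#' @param beta0_mean,beta0_sd distribution of the calibration intercept.
#' @param beta1_mean,beta1_sd distribution of the calibration slope.
#' @param noise_sd trial rating noise SD (rating points).
#' @param curve a [pitch_bias_curve()].
#' @param tap_design `"between"` assigns half the subjects to tap,
#'   `"none"` disables the manipulation.
#' @param tap_failure_prob probability an instructed tapper fails to tap on
#'   a trial.
#' @param responder_mix named proportions for `compliant`, `anchor`
#'   (nearest-anchor responses in {0, 50, 100}) and `inverted`
#'   (reversed scale) types.
#' @param seed master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 193, pitches = pitch_set_octaves(),
                       grid = log_spaced_iois(1000, 302, 15),
                       n_blocks = 3L,
                       beta0_mean = 50, beta0_sd = 3,
                       beta1_mean = 50, beta1_sd = 10,
                       noise_sd = 8,
                       curve = pitch_bias_curve(),
                       tap_design = c("between", "none"),
                       tap_failure_prob = 0.276,
                       responder_mix = c(compliant = 1, anchor = 0,
                                         inverted = 0),
                       seed = 1L) {
  tap_design <- match.arg(tap_design)
  mix <- responder_mix / sum(responder_mix)
  if (any(mix < 0)) stop("responder_mix must be nonnegative", call. = FALSE)
  if (tap_failure_prob < 0 || tap_failure_prob > 1)
    stop("tap_failure_prob must lie in [0, 1]", call. = FALSE)
  if (!setequal(curve$codes, pitches$codes))
    stop("curve codes must match the pitch set", call. = FALSE)
  structure(list(n_subjects = n_subjects, pitches = pitches, grid = grid,
                 n_blocks = as.integer(n_blocks),
                 beta0_mean = beta0_mean, beta0_sd = beta0_sd,
                 beta1_mean = beta1_mean, beta1_sd = beta1_sd,
                 noise_sd = noise_sd, curve = curve,
                 tap_design = tap_design,
                 tap_failure_prob = tap_failure_prob,
                 responder_mix = mix, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one rater
#'
#' Generates a constrained trial plan and ratings from the generative
#' inverse of the scoring model: the true pitch bias enters additively on
#' the log2-tempo axis (divided by 100) before scaling by the subject's
#' slope, so with zero noise the scoring pipeline recovers the injected
#' curve exactly:
#' \deqn{r_i = \beta_0 + \beta_1 (\log_2(t_i/t_{ref}) +
#'       curve(pitch_i)/100) + \epsilon_i}
#' Ratings are clipped to the 0--100 slider. Anchor-only responders return
#' the anchor in {0, 50, 100} nearest their underlying rating; inverted
#' responders return 100 minus it.
#'
#' @param config a [sim_config()].
#' @param subject_seed integer seed for this subject.
#' @param participant_id id string.
#' @param tap_instruction `"tap"`, `"no_tap"` or `"n/a"`.
#' @param responder_type `"compliant"`, `"anchor"` or `"inverted"`.
#' @param beta0,beta1 optionally fix the subject's true coefficients.
#' @return list: `trials` (data.frame) and `truth` (one-row data.frame with
#'   the generating parameters).
#' @export
simulate_rater <- function(config, subject_seed,
                           participant_id = "S001",
                           tap_instruction = "n/a",
                           responder_type = "compliant",
                           beta0 = NULL, beta1 = NULL) {
  stopifnot(inherits(config, "sim_config"))
  plan <- randomize_trials(config$pitches, config$grid,
                           n_blocks = config$n_blocks,
                           seed = subject_seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(subject_seed %% .Machine$integer.max)
  if (is.null(beta0)) beta0 <- stats::rnorm(1, config$beta0_mean, config$beta0_sd)
  if (is.null(beta1)) beta1 <- stats::rnorm(1, config$beta1_mean, config$beta1_sd)
  x <- log2(config$grid$ref_ioi_ms / plan$ioi_ms)
  bias <- curve_at(config$curve, plan$pitch_code)
  eps <- if (config$noise_sd > 0)
    stats::rnorm(nrow(plan), 0, config$noise_sd) else 0
  rating <- beta0 + beta1 * (x + bias / 100) + eps
  rating <- pmax(0, pmin(100, rating))
  if (responder_type == "anchor") {
    anchors <- c(0, 50, 100)
    rating <- anchors[max.col(-abs(outer(rating, anchors, `-`)))]
  } else if (responder_type == "inverted") {
    rating <- 100 - rating
  }
  tapped <- if (tap_instruction == "tap")
    stats::runif(nrow(plan)) > config$tap_failure_prob else NA
  trials <- data.frame(
    participant_id = participant_id,
    tap_instruction = tap_instruction,
    block = plan$block, trial = plan$trial,
    pitch_label = plan$pitch_label, pitch_code = plan$pitch_code,
    f0_hz = plan$f0_hz, ioi_ms = plan$ioi_ms,
    loudness_db = plan$loudness_db,
    rating = rating, tapped = tapped,
    stringsAsFactors = FALSE)
  truth <- data.frame(participant_id = participant_id,
                      beta0 = beta0, beta1 = beta1,
                      responder_type = responder_type,
                      tap_instruction = tap_instruction,
                      stringsAsFactors = FALSE)
  list(trials = trials, truth = truth)
}

#' Simulate a full study
#'
#' Draws each subject's responder type from the configured mix, assigns tap
#' instructions (alternating, for a balanced between-subjects split), and
#' concatenates per-subject simulations. Fully reproducible from the master
#' seed; the truth ledger is returned separately from the trial table so
#' the analysis path cannot touch it.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_study`: `trials` (all subjects) and `truth`
#'   (per-subject ledger: generating coefficients, responder type, tap
#'   assignment), plus the config.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)
  subject_seeds <- sample.int(2^31 - 2, n)
  types <- sample(names(config$responder_mix), n, replace = TRUE,
                  prob = config$responder_mix)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  taps <- if (config$tap_design == "between")
    rep(c("tap", "no_tap"), length.out = n) else rep("n/a", n)
  ids <- sprintf("S%03d", seq_len(n))
  sims <- lapply(seq_len(n), function(i)
    simulate_rater(config, subject_seeds[i], ids[i], taps[i], types[i]))
  structure(list(
    trials = do.call(rbind, lapply(sims, `[[`, "trials")),
    truth = do.call(rbind, lapply(sims, `[[`, "truth")),
    config = config), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d subjects, %d trials each (%d total)\n",
              nrow(x$truth), nrow(x$trials) / nrow(x$truth),
              nrow(x$trials)))
  invisible(x)
}
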