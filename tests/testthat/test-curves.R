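test_that("orthogonal basis is orthonormal and matches stats::poly", {
  b <- ortho_basis(2:7, 5)
  expect_equal(crossprod(b$P), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(colSums(b$P), rep(0, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # linear column proportional to centered codes
  cc <- 2:7 - mean(2:7)
  expect_equal(b$P[, 1], cc / sqrt(sum(cc^2)), ignore_attr = TRUE,
               tolerance = 1e-12)
  # same subspace and columns as R's own orthogonal polynomials (up to sign)
  ref <- unclass(stats::poly(2:7, 5))
  for (j in 1:5)
    expect_equal(abs(b$P[, j]), abs(ref[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  expect_error(ortho_basis(2:7, 6), "degree")
})

test_that("lower-degree bases nest inside higher-degree ones", {
  b2 <- ortho_basis(2:7, 2)
  b5 <- ortho_basis(2:7, 5)
  expect_equal(b2$P, b5$P[, 1:2], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pitch curve fitting aligns with the basis", {
  b <- ortho_basis(2:7, 5)
  codes <- rep(2:7, each = 15)
  # tau exactly quadratic in the basis: only c2 is nonzero
  tau <- -3 * b$P[match(codes, b$codes), 2]
  f <- fit_pitch_curve(tau, codes, b)
  expect_equal(unname(f$coef["P2"]), -3, tolerance = 1e-9)
  expect_lt(max(abs(f$coef[-2])), 1e-9)
  expect_lt(abs(f$intercept), 1e-9)
  # zero data, zero coefficients
  f0 <- fit_pitch_curve(rep(0, length(codes)), codes, b)
  expect_lt(max(abs(f0$coef)), 1e-12)
  expect_error(fit_pitch_curve(tau[codes != 4], codes[codes != 4], b),
               "missing pitch level")
})

test_that("full-trial fits have zero intercept on balanced data", {
  st <- simulate_study(sim_config(n_subjects = 40, seed = 61))
  # with no trials excluded the pitch design stays balanced, so the
  # intercept equals the (zero) mean shift exactly
  sc <- score_shifts(st$trials, cooks_multiplier = Inf)
  b <- ortho_basis(2:7, 5)
  curves <- fit_curves_by_participant(sc$shifts, b)
  expect_lt(max(abs(curves$intercept)), 1e-9)
  expect_equal(ncol(curves), 3 + 5)
  # outlier exclusion unbalances the design slightly; the intercept stays
  # near zero but is no longer an exact identity
  sc2 <- score_shifts(st$trials)
  curves2 <- fit_curves_by_participant(sc2$shifts, b)
  expect_lt(max(abs(curves2$intercept)), 1)
})

test_that("coefficient t-statistics are invariant to affine recoding", {
  st <- simulate_study(sim_config(n_subjects = 25, seed = 71))
  sc <- score_shifts(st$trials)
  fit_t <- function(shifts, offset) {
    codes <- sort(unique(shifts$pitch_code)) + offset
    b <- ortho_basis(codes, 2)
    s2 <- shifts
    s2$pitch_code <- s2$pitch_code + offset
    cur <- fit_curves_by_participant(s2, b)
    X <- as.matrix(cur[, c("c1", "c2")])
    colMeans(X) / (apply(X, 2, sd) / sqrt(nrow(X)))
  }
  expect_equal(fit_t(sc$shifts, 0), fit_t(sc$shifts, 10), tolerance = 1e-9)
})

test_that("condition-sliced fits work and share curves on noise-free data", {
  g <- paper_grid()
  bins <- tempo_range_bins(g)
  b <- ortho_basis(2:7, 2)
  codes <- rep(2:7, each = 15)
  iois <- rep(g$iois_ms, times = 6)
  shifts <- data.frame(
    participant_id = "S001", pitch_code = codes, ioi_ms = iois,
    tempo_range = bins[match(iois, g$iois_ms)],
    tau = 2 * b$P[match(codes, b$codes), 1] - 4 * b$P[match(codes, b$codes), 2],
    is_outlier = FALSE)
  out <- fit_condition_curves(shifts, "tempo_range", b)
  expect_equal(nrow(out), 5)
  expect_true(all(out$n_trials == 18))
  expect_equal(out$c1, rep(2, 5), tolerance = 1e-9)
  expect_equal(out$c2, rep(-4, 5), tolerance = 1e-9)
  # a slice that loses a pitch level errors with a message naming it
  broken <- shifts[!(shifts$tempo_range == 3 & shifts$pitch_code == 4), ]
  expect_error(fit_condition_curves(broken, "tempo_range", b),
               "slice tempo_range = 3")
})

test_that("failed-tap exclusion removes about the configured fraction", {
  st <- simulate_study(sim_config(n_subjects = 120, seed = 81))
  tap <- st$trials[st$trials$tap_instruction == "tap", ]
  expect_equal(mean(tap$tapped), 1 - 0.276, tolerance = 0.02)
})

test_that("within-subject intervals remove offsets and demand complete data", {
  profile <- c(1, 3, 2, 5)
  offsets <- scale(rnorm(12), scale = FALSE)  # mean-zero subject offsets
  vals <- t(replicate(12, profile)) + as.vector(offsets)
  ci <- within_subject_ci(vals)
  expect_lt(max(ci$upper - ci$lower), 1e-9)
  expect_equal(ci$mean, profile, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(within_subject_ci(matrix(1:5, ncol = 1)), "at least 2")
  bad <- vals; bad[1, 2] <- NA
  expect_error(within_subject_ci(bad), "missing")
})

test_that("within-subject intervals have near-nominal contrast coverage", {
  # the intervals describe condition differences: check that the implied
  # CI on a pairwise contrast covers the true difference ~95% of the time
  set.seed(91)
  n <- 15; k <- 4
  mu <- c(0, 1, 2, 3)
  hits <- 0; reps <- 400
  for (r in seq_len(reps)) {
    vals <- matrix(rnorm(n * k, sd = 1), n, k) +
      rnorm(n, sd = 3) +                # subject offsets, removed by design
      matrix(mu, n, k, byrow = TRUE)
    ci <- within_subject_ci(vals)
    jk <- sample(k, 2)
    diff_true <- mu[jk[1]] - mu[jk[2]]
    se_diff <- sqrt(ci$se[jk[1]]^2 + ci$se[jk[2]]^2)
    ctr <- ci$mean[jk[1]] - ci$mean[jk[2]]
    tcrit <- qt(0.975, n - 1)
    hits <- hits + (abs(ctr - diff_true) <= tcrit * se_diff)
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})
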