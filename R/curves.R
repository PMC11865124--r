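#' Orthonormal polynomial basis over pitch codes
#'
#' Builds degree-`d` orthogonal polynomial contrast columns over a set of
#' consecutive integer codes by QR-orthonormalizing the Vandermonde matrix
#' (constant column included then dropped). Columns have unit norm, are
#' mutually orthogonal and orthogonal to the constant, and are sign-fixed so
#' that column j correlates positively with `codes^j` (the linear column
#' increases with code; the quadratic opens upward).
#'
#' @param codes distinct consecutive integer codes (e.g., `2:7`).
#' @param degree polynomial degree; must be below the number of codes.
#' @return object of class `ortho_basis` with `codes`, `degree`, and the
#'   basis matrix `P` (one row per code, columns `P1..Pd`).
#' @export
ortho_basis <- function(codes, degree = 5L) {
  codes <- sort(unique(as.numeric(codes)))
  k <- length(codes)
  if (degree >= k)
    stop("degree must be below the number of distinct codes", call. = FALSE)
  if (degree < 1) stop("degree must be at least 1", call. = FALSE)
  V <- cbind(1, outer(codes, seq_len(degree), `^`))
  Q <- qr.Q(qr(V))[, -1, drop = FALSE]
  for (j in seq_len(degree)) {
    if (sum(Q[, j] * codes ^ j) < 0) Q[, j] <- -Q[, j]
  }
  colnames(Q) <- paste0("P", seq_len(degree))
  rownames(Q) <- codes
  structure(list(codes = codes, degree = as.integer(degree), P = Q),
            class = "ortho_basis")
}

# basis rows matched to a vector of trial-level codes
basis_rows <- function(basis, codes) {
  idx <- match(codes, basis$codes)
  if (anyNA(idx))
    stop("codes outside the basis: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
  basis$P[idx, , drop = FALSE]
}

#' Fit one participant's illusory tempo curve over pitch
#'
#' Least-squares regression of illusory shift on the orthogonal polynomial
#' basis (with intercept). When fit to all of a participant's included
#' trials the intercept is zero up to rounding, because the mean shift is
#' zero by construction. Every pitch level in the basis must be present.
#'
#' @param tau illusory shifts (log2-percent), included trials only.
#' @param codes pitch code per trial.
#' @param basis an [ortho_basis()].
#' @return object of class `poly_curve_fit`: `coef` (c1..cd), `intercept`,
#'   `degree`, `n_trials`.
#' @export
fit_pitch_curve <- function(tau, codes, basis) {
  stopifnot(inherits(basis, "ortho_basis"))
  if (length(tau) != length(codes))
    stop("tau and codes must match in length", call. = FALSE)
  missing_lvl <- setdiff(basis$codes, unique(codes))
  if (length(missing_lvl) > 0)
    stop("missing pitch level(s): ", paste(missing_lvl, collapse = ", "),
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, basis_rows(basis, codes))
  cf <- stats::lm.fit(X, tau)$coefficients
  structure(list(coef = cf[-1], intercept = unname(cf[1]),
                 degree = basis$degree, n_trials = length(tau)),
            class = "poly_curve_fit")
}

#' @export
print.poly_curve_fit <- function(x, ...) {
  cat(sprintf("Pitch curve (degree %d, %d trials): intercept %.4g\n",
              x$degree, x$n_trials, x$intercept))
  print(round(x$coef, 4))
  invisible(x)
}

#' Per-participant curve coefficients
#'
#' Fits [fit_pitch_curve()] to every participant's included trials and
#' returns the coefficient matrix used by the group-level multivariate
#' tests.
#'
#' @param shifts scored trial table (the `shifts` element of
#'   [score_shifts()]); rows with `is_outlier = TRUE` are dropped.
#' @param basis an [ortho_basis()].
#' @return data.frame: `participant_id`, `intercept`, `c1..cd`, `n_trials`.
#' @export
fit_curves_by_participant <- function(shifts, basis) {
  stopifnot(all(c("participant_id", "pitch_code", "tau") %in% names(shifts)))
  if ("is_outlier" %in% names(shifts))
    shifts <- shifts[!shifts$is_outlier, , drop = FALSE]
  ids <- unique(shifts$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- shifts[shifts$participant_id == id, ]
    f <- fit_pitch_curve(tr$tau, tr$pitch_code, basis)
    out <- data.frame(participant_id = id, intercept = f$intercept,
                      n_trials = f$n_trials, stringsAsFactors = FALSE)
    for (j in seq_along(f$coef)) out[[paste0("c", j)]] <- unname(f$coef[j])
    out
  })
  do.call(rbind, rows)
}

#' Condition-sliced curve fits
#'
#' Fits one polynomial curve per participant per level of a slicing column
#' (tempo range, timbre, register, tap condition, ...). For tap analyses,
#' exclude failed-tap trials from `shifts` before calling. A slice that is
#' empty or loses a pitch level raises an error naming the participant and
#' slice rather than silently refitting a reduced-rank model.
#'
#' @param shifts scored trial table; outlier rows are dropped.
#' @param slice_by name of the column to slice on.
#' @param basis an [ortho_basis()] (typically degree 2 for sliced fits).
#' @return data.frame: `participant_id`, `slice`, `intercept`, `c1..cd`,
#'   `n_trials`.
#' @export
fit_condition_curves <- function(shifts, slice_by, basis) {
  stopifnot(slice_by %in% names(shifts))
  if ("is_outlier" %in% names(shifts))
    shifts <- shifts[!shifts$is_outlier, , drop = FALSE]
  ids <- unique(shifts$participant_id)
  levels_all <- sort(unique(shifts[[slice_by]]))
  rows <- list()
  for (id in ids) {
    tr <- shifts[shifts$participant_id == id, ]
    for (lv in levels_all) {
      sl <- tr[tr[[slice_by]] == lv, ]
      if (nrow(sl) == 0)
        stop("participant ", id, ": empty slice ", slice_by, " = ", lv,
             call. = FALSE)
      f <- tryCatch(fit_pitch_curve(sl$tau, sl$pitch_code, basis),
                    error = function(e)
                      stop("participant ", id, ", slice ", slice_by, " = ",
                           lv, ": ", conditionMessage(e), call. = FALSE))
      out <- data.frame(participant_id = id, slice = lv,
                        intercept = f$intercept, n_trials = f$n_trials,
                        stringsAsFactors = FALSE)
      for (j in seq_along(f$coef)) out[[paste0("c", j)]] <- unname(f$coef[j])
      rows[[length(rows) + 1L]] <- out
    }
  }
  do.call(rbind, rows)
}

#' Within-subject confidence intervals (Cousineau--Morey)
#'
#' Normalizes a complete subject x condition table by removing each
#' subject's mean and adding back the grand mean, scales deviations from
#' the condition means by the bias-correction factor sqrt(k/(k-1)), and
#' returns t-based intervals per condition. These intervals describe
#' condition differences, not absolute levels.
#'
#' @param values numeric matrix, one row per subject, one column per
#'   condition (no missing cells; at least 2 conditions).
#' @param level confidence level.
#' @return data.frame: `condition`, `mean`, `lower`, `upper`, `se`.
#' @export
within_subject_ci <- function(values, level = 0.95) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells", call. = FALSE)
  k <- ncol(values)
  n <- nrow(values)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  norm <- values - rowMeans(values) + mean(values)
  cm <- colMeans(norm)
  dev <- sweep(norm, 2, cm)
  dev <- dev * sqrt(k / (k - 1))  # Morey correction
  se <- apply(dev, 2, stats::sd) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  data.frame(condition = colnames(values) %||% seq_len(k),
             mean = cm, lower = cm - tcrit * se, upper = cm + tcrit * se,
             se = se, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
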