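# Shared fixtures, built in code.

paper_grid <- function() log_spaced_iois(1000, 302, 15)

# the published IOI and BPM tables for the 1000..302 grid
PUBLISHED_IOIS <- c(1000, 918, 843, 774, 710, 652, 599, 550, 504, 463,
                    425, 390, 358, 329, 302)
PUBLISHED_BPMS <- c(60.0, 65.4, 71.2, 77.5, 84.5, 92.0, 100.2, 109.1,
                    119.0, 129.6, 141.2, 153.8, 167.6, 182.4, 199.7)

# noiseless single-subject trial table following the ground-truth line
# exactly (one trial per pitch x tempo)
noiseless_trials <- function(beta0 = 50, beta1 = 50, id = "S001") {
  g <- paper_grid()
  ps <- pitch_set_octaves()
  df <- expand.grid(ioi_ms = g$iois_ms, pitch_code = ps$codes)
  x <- log2(g$ref_ioi_ms / df$ioi_ms)
  data.frame(participant_id = id,
             pitch_code = df$pitch_code,
             ioi_ms = df$ioi_ms,
             loudness_db = 0,
             rating = beta0 + beta1 * x,
             stringsAsFactors = FALSE)
}

# independent leave-one-out Cook's distance oracle: distance measured from
# the coefficient change on deleting each observation
cooks_loo_oracle <- function(x, y) {
  X <- cbind(1, x)
  n <- length(y)
  beta <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% beta)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    bi <- solve(crossprod(X[-i, ]), crossprod(X[-i, ], y[-i]))
    db <- beta - bi
    as.numeric(t(db) %*% crossprod(X) %*% db) / (2 * s2)
  }, numeric(1))
}
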