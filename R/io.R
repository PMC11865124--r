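#' Read a trial table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header. Required columns:
#' `participant_id`, `pitch_code`, `ioi_ms`, `loudness_db`, `rating`.
#' Optional columns (`experiment`, `tap_instruction`, `timbre`, `register`,
#' `block`, `trial`, `pitch_label`, `f0_hz`, `tapped`, `practice`) pass
#' through; missing optional columns are filled with neutral defaults.
#' Practice trials (`practice = TRUE`) are dropped: they never enter
#' analysis. Malformed rows are reported with their line numbers.
#'
#' @param path CSV file.
#' @return validated trial data.frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "pitch_code", "ioi_ms", "loudness_db",
                "rating")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$rating) | df$rating < 0 | df$rating > 100)
  if (length(bad) > 0)
    stop("rating out of [0, 100] at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$ioi_ms) | df$ioi_ms <= 0)
  if (length(bad) > 0)
    stop("non-positive ioi_ms at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  defaults <- list(experiment = "n/a", tap_instruction = "n/a",
                   timbre = "n/a", register = "full", practice = FALSE)
  for (col in names(defaults))
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  df[!as.logical(df$practice), , drop = FALSE]
}

#' Write a trial table to CSV
#' @param trials trial data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an analysis result to JSON with provenance
#'
#' Every results artifact embeds the configuration hash and seed so runs
#' can be traced back to their inputs.
#'
#' @param result named list of results (coerced via jsonlite).
#' @param path output file.
#' @param config list serialized alongside (hashed into `config_hash`).
#' @param seed seed recorded in the artifact.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(result, path, config = list(), seed = NA) {
  payload <- list(config_hash = config_hash(config), seed = seed,
                  results = result)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' FNV-1a over the canonical JSON serialization; dependency-free and stable
#' across sessions for plain lists.
#'
#' @param config a list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply split into 16-bit halves to stay exact in
    # double precision
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (((h_hi * p) %% 65536) * 65536 + h_lo * p) %% 4294967296
  }
  lo <- as.integer(h %% 65536)
  hi <- as.integer((h - lo) / 65536)
  sprintf("%04x%04x", hi, lo)
}
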