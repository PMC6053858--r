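# Trial-log round-tripping, replay inference, configuration files and
# result serialisation.

LOG_VERSION <- "drt_trial_log v1"
LOG_COLUMNS <- c("index", "phase", "f_mask_hz", "l_mask_db_hl", "is_catch",
                 "response", "mi_bits", "fe_map_cam",
                 "posterior_entropy_bits", "rng_call_count", "sd_db")

#' Write a session trial log to CSV
#'
#' One row per presented trial, numeric fields serialised at 17
#' significant digits so that reading the file back reproduces the values
#' exactly. The first line is a version comment.
#'
#' @param trials The `trials` data frame of a `"drt_session"`.
#' @param path File path.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(all(LOG_COLUMNS %in% names(trials)))
  d <- trials[, LOG_COLUMNS]
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    else as.character(x)
  }
  out <- vapply(d, fmt, character(nrow(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", LOG_VERSION), con)
  writeLines(paste(LOG_COLUMNS, collapse = ","), con)
  writeLines(apply(matrix(out, nrow(d)), 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a session trial log
#'
#' Validates the version line, the column set, and per-row field types;
#' malformed rows are reported by number.
#'
#' @param path File path.
#' @return A trial data frame as produced by [run_session()].
#' @export
read_trial_log <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("# ", LOG_VERSION)))
    stop("trial-log version mismatch: expected '", LOG_VERSION,
         "', found '", sub("^# ", "", first), "'")
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = "character")
  if (!identical(names(d), LOG_COLUMNS))
    stop("trial log columns do not match: ",
         paste(names(d), collapse = ","))
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(ifelse(d[[col]] == "NA", NA, d[[col]])))
    bad <- which(is.na(v) & d[[col]] != "NA")
    if (length(bad))
      stop(sprintf("trial log row %d: non-numeric %s '%s'",
                   bad[1], col, d[[col]][bad[1]]))
    v
  }
  parse_bool <- function(col) {
    ok <- d[[col]] %in% c("TRUE", "FALSE", "NA")
    if (!all(ok))
      stop(sprintf("trial log row %d: non-boolean %s '%s'",
                   which(!ok)[1], col, d[[col]][which(!ok)[1]]))
    as.logical(d[[col]])
  }
  data.frame(
    index = as.integer(parse_num("index")),
    phase = d$phase,
    f_mask_hz = parse_num("f_mask_hz"),
    l_mask_db_hl = parse_num("l_mask_db_hl"),
    is_catch = parse_bool("is_catch"),
    response = parse_bool("response"),
    mi_bits = parse_num("mi_bits"),
    fe_map_cam = parse_num("fe_map_cam"),
    posterior_entropy_bits = parse_num("posterior_entropy_bits"),
    rng_call_count = as.integer(parse_num("rng_call_count")),
    sd_db = parse_num("sd_db"),
    stringsAsFactors = FALSE)
}

#' Recompute the posterior from a logged session
#'
#' Inference-only replay: practice and catch trials are skipped, every
#' other trial updates the posterior in logged order (using each trial's
#' logged slope parameter where present). Because the likelihood is
#' exchangeable, a replayed log reproduces the live session's estimates
#' exactly.
#'
#' @param trials A trial data frame (from a log or a session).
#' @param a The `"audiogram"` of the tested ear.
#' @param sig The `"signal_spec"` used in the session.
#' @param sd Slope parameter for rows without a logged `sd_db`.
#' @param lapse Lapse rate.
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @return A list of class `"drt_replay"` with `fe_map_trace`,
#'   `final_fe_cam`, `final_fe_hz` and `posterior`.
#' @export
replay_estimate <- function(trials, a, sig, sd = 3, lapse = 0.01,
                            ten_floor = 35) {
  post <- build_prior(a, sig)
  inf <- which(!trials$is_catch & trials$phase != "practice" &
                 !is.na(trials$response))
  if (!length(inf)) stop("log contains no inference trials")
  trace <- numeric(length(inf))
  for (j in seq_along(inf)) {
    i <- inf[j]
    sd_i <- if (!is.null(trials$sd_db) && !is.na(trials$sd_db[i]))
      trials$sd_db[i] else sd
    post <- update_posterior(
      post,
      list(x = list(f_mask = trials$f_mask_hz[i],
                    l_mask = trials$l_mask_db_hl[i]),
           y = trials$response[i]),
      sig, a, sd_i, lapse, ten_floor)
    trace[j] <- map_fe(post)
  }
  structure(list(fe_map_trace = trace, final_fe_cam = trace[length(trace)],
                 final_fe_hz = hz_from_cam(trace[length(trace)]),
                 posterior = post),
            class = "drt_replay")
}

CONFIG_KEYS <- c("session", "paths", "mode")
PATH_KEYS <- c("audiogram", "profile", "log", "out")

#' Read a run-configuration file
#'
#' YAML with up to three blocks: `session` (any [session_config()]
#' argument), `paths` (`audiogram`, `profile`, `log`, `out`) and `mode`
#' (`simulate` or `replay`). Unknown keys are rejected; defaults are
#' applied only for absent keys and the fully resolved configuration is
#' returned.
#'
#' @param path File path.
#' @return List with `session` (a `"drt_config"`), `paths`, `mode`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  sess <- raw$session
  if (!is.null(sess)) {
    bad <- setdiff(names(sess), names(formals(session_config)))
    if (length(bad))
      stop("unknown session key(s): ", paste(bad, collapse = ", "))
  }
  paths <- raw$paths
  if (!is.null(paths)) {
    bad <- setdiff(names(paths), PATH_KEYS)
    if (length(bad))
      stop("unknown path key(s): ", paste(bad, collapse = ", "))
  }
  mode <- raw$mode
  if (is.null(mode)) mode <- "simulate"
  if (!mode %in% c("simulate", "replay"))
    stop("mode must be 'simulate' or 'replay'")
  list(session = do.call(session_config, as.list(sess)),
       paths = paths, mode = mode)
}

#' Serialise a session result to JSON
#'
#' Writes the configuration echo, the final estimate in Cams and Hz, the
#' per-trial traces and the flags, with numbers at 12 significant digits
#' for cross-platform reproducibility of the file text.
#'
#' @param session A `"drt_session"`.
#' @param path File path.
#' @export
write_session_json <- function(session, path) {
  cfg <- session$config
  out <- list(
    config = unclass(cfg),
    final_fe_cam = session$final_fe_cam,
    final_fe_hz = session$final_fe_hz,
    n_trials_presented = nrow(session$trials),
    n_inference_trials = length(session$fe_map_trace),
    fe_map_trace_cam = session$fe_map_trace,
    mi_trace_bits = session$mi_trace,
    flags = as.list(session$flags),
    stopped_early = isTRUE(session$stopped))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a listener profile to JSON (audiogram inline)
#'
#' @param profile A `"listener_profile"`.
#' @param path File path.
#' @export
write_profile_json <- function(profile, path) {
  out <- list(
    label = profile$label,
    true_fe_hz = profile$true_fe_hz,
    true_ohcl_db = profile$true_ohcl,
    psych_sd_db = profile$psych_sd,
    false_alarm_rate = profile$false_alarm_rate,
    lapse = profile$lapse,
    broadening = profile$broadening,
    audiogram = list(frequency_hz = profile$audiogram$frequency_hz,
                     hl_total_db = profile$audiogram$hl_db,
                     ear = profile$audiogram$ear))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

#' Read a listener profile from JSON
#'
#' The audiogram may be inline (`frequency_hz` + `hl_total_db`) or a
#' `file` reference to an audiogram CSV, resolved relative to the profile
#' file.
#'
#' @param path File path.
#' @return A `"listener_profile"`.
#' @export
read_profile_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  ag <- p$audiogram
  a <- if (!is.null(ag$file)) {
    read_audiogram(file.path(dirname(path), ag$file),
                   ear = ag$ear %||% "")
  } else {
    audiogram(ag$frequency_hz, ag$hl_total_db, ear = ag$ear %||% "")
  }
  listener_profile(true_fe_hz = p$true_fe_hz, true_ohcl = p$true_ohcl_db,
                   audiogram = a, psych_sd = p$psych_sd_db %||% 3,
                   false_alarm_rate = p$false_alarm_rate %||% 0.01,
                   lapse = p$lapse %||% 0.01,
                   broadening = p$broadening %||% 1,
                   label = p$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
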