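# Simulated listeners.
#
# The responder is the generative counterpart of the detection likelihood:
# on signal trials it answers yes with the hit probability evaluated at
# its true parameters; on catch trials it answers yes at its false-alarm
# rate. A cohort generator produces sloping high-frequency losses covering
# the edge-frequency and audiogram-slope ranges the test is meant for.

#' Construct a simulated listener profile
#'
#' @param true_fe_hz True edge frequency (Hz).
#' @param true_ohcl True outer-hair-cell loss at the edge (dB); must not
#'   exceed the audiogram's HL_total at `true_fe_hz`.
#' @param audiogram An `"audiogram"`.
#' @param psych_sd Psychometric slope parameter in dB (3 for typical
#'   listeners, about 10 for unreliable ones).
#' @param false_alarm_rate Probability of yes on a catch trial, in
#'   \[0, 0.5\]; around 0.1-0.17 emulates tinnitus.
#' @param lapse Lapse rate used generatively.
#' @param broadening Filter-broadening multiplier; values away from 1
#'   make the responder's ear deviate from the inference model
#'   (model-mismatch probe).
#' @param label Free-text label.
#' @return A list of class `"listener_profile"`.
#' @export
listener_profile <- function(true_fe_hz, true_ohcl, audiogram,
                             psych_sd = 3, false_alarm_rate = 0.01,
                             lapse = 0.01, broadening = 1, label = "") {
  stopifnot(inherits(audiogram, "audiogram"), true_fe_hz > 0,
            psych_sd > 0, lapse >= 0, lapse < 0.5)
  if (false_alarm_rate < 0 || false_alarm_rate > 0.5)
    stop("false_alarm_rate must lie within [0, 0.5]")
  hl_fe <- interpolate_hl(audiogram, true_fe_hz)
  if (true_ohcl < 0 || true_ohcl > hl_fe + 1e-9)
    stop("true_ohcl must lie within [0, HL_total(true_fe)]")
  structure(list(true_fe_hz = true_fe_hz, true_ohcl = true_ohcl,
                 audiogram = audiogram, psych_sd = psych_sd,
                 false_alarm_rate = false_alarm_rate, lapse = lapse,
                 broadening = broadening, label = label),
            class = "listener_profile")
}

#' @export
print.listener_profile <- function(x, ...) {
  cat(sprintf(paste0("Simulated listener %s: f_e %.0f Hz (%.2f Cams), ",
                     "OHCL %.1f dB, sd %.1f dB, FA %.0f%%\n"),
              x$label, x$true_fe_hz, cam_from_hz(x$true_fe_hz),
              x$true_ohcl, x$psych_sd, 100 * x$false_alarm_rate))
  invisible(x)
}

#' Simulated yes/no response to one trial
#'
#' Catch trials: Bernoulli at the false-alarm rate. Signal trials:
#' Bernoulli at the hit probability under the listener's true parameters
#' (including any filter-broadening mismatch). Consumes one draw from the
#' current RNG stream, so fixed seeds give identical response sequences.
#'
#' @param profile A `"listener_profile"`.
#' @param x Stimulus: list with `f_mask`, `l_mask`.
#' @param sig A `"signal_spec"`.
#' @param is_catch Logical: signal omitted on this trial.
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @return Logical yes/no.
#' @export
respond <- function(profile, x, sig, is_catch = FALSE, ten_floor = 35) {
  stopifnot(inherits(profile, "listener_profile"))
  if (is_catch) return(stats::runif(1) < profile$false_alarm_rate)
  hl_fe <- interpolate_hl(profile$audiogram, profile$true_fe_hz)
  d <- .cell_excitation_diff(profile$true_fe_hz, profile$true_ohcl, hl_fe,
                             x$f_mask, x$l_mask, sig, ten_floor,
                             broadening = profile$broadening)
  p <- profile$lapse +
    (1 - 2 * profile$lapse) * stats::pnorm(d / profile$psych_sd)
  stats::runif(1) < p
}

#' Responder closure for [run_session()]
#'
#' @param profile A `"listener_profile"`.
#' @param sig A `"signal_spec"`.
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @return Function `(x, is_catch)` returning logical.
#' @export
make_responder <- function(profile, sig, ten_floor = 35) {
  force(profile); force(sig); force(ten_floor)
  function(x, is_catch) respond(profile, x, sig, is_catch, ten_floor)
}

#' Responder closure for the quick TEN(HL) screening test
#'
#' Detection of the probe in broadband TEN is modelled with the same
#' likelihood: the listener attends the place with the best
#' signal-to-noise ratio, which is the edge place when the probe falls in
#' the dead region and the probe's own place otherwise.
#'
#' @param profile A `"listener_profile"`.
#' @return Function `(f_sig, l_sig, ten_level, is_catch)` returning
#'   logical.
#' @export
make_ten_responder <- function(profile) {
  force(profile)
  function(f_sig, l_sig, ten_level, is_catch) {
    if (is_catch) return(stats::runif(1) < profile$false_alarm_rate)
    a <- profile$audiogram
    cf <- min(f_sig, profile$true_fe_hz)
    cf <- min(max(cf, min(a$frequency_hz)), max(a$frequency_hz))
    hl_cf <- interpolate_hl(a, cf)
    ohcl_cf <- min(profile$true_ohcl, hl_cf)
    shape <- filter_slopes(cf, min(110, ten_level), ohcl_cf,
                           broadening = profile$broadening)
    e_sig <- excitation_tone(shape, f_sig, l_sig)
    e_ten <- ten_excitation(shape, ten_level)
    d <- e_sig - max(e_ten, hl_cf)
    p <- profile$lapse +
      (1 - 2 * profile$lapse) * stats::pnorm(d / profile$psych_sd)
    stats::runif(1) < p
  }
}

#' Generate a simulated cohort
#'
#' Produces `n_profiles` listeners with sigmoidal (on the Cam axis)
#' high-frequency losses: a low-frequency plateau of 10-40 dB HL, a
#' high-frequency plateau of 80-110 dB HL, and an audiogram slope at the
#' 65-dB-HL point log-spread over 14-145 dB/octave. True edge frequencies
#' are log-spread over 0.5-3.3 kHz; OHCL is drawn uniformly between 10 dB
#' and HL_total(f_e) (capped at 65 dB). The distance from the edge to the
#' 65-dB-HL point is chosen, per profile, as the largest value in
#' \[0.8, 2.5\] Cams that keeps the 10-dB-SL probe audible in quiet by at
#' least 3 dB at the edge place, mirroring the audibility check a real
#' protocol performs before testing. Most listeners respond with a 3-dB
#' slope and 1% false alarms; two are slope outliers near 10 dB and two
#' have tinnitus-like false-alarm rates of 17% and 10%.
#'
#' The caller's RNG state is restored on exit, so the cohort depends only
#' on `seed`.
#'
#' @param seed Integer seed.
#' @param n_profiles Number of listeners (>= 12).
#' @return List of `"listener_profile"` objects.
#' @export
generate_cohort <- function(seed = 1, n_profiles = 12) {
  if (n_profiles < 12) stop("the cohort design needs at least 12 profiles")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- n_profiles
  fe <- exp(seq(log(500), log(3300), length.out = n)) *
    exp(stats::runif(n, -0.04, 0.04))
  slope_oct <- sample(exp(seq(log(14), log(145), length.out = n)))
  lo <- stats::runif(n, 10, 40)
  hi <- stats::runif(n, 80, 110)
  psych_sd <- rep(3, n)
  fa <- rep(0.01, n)
  psych_sd[c(n - 2L, n - 1L)] <- 10   # slope outliers
  fa[n - 1L] <- 0.17                  # tinnitus-like, also slope outlier
  fa[n] <- 0.10                       # tinnitus-like, normal slope
  cam_pts <- seq(2.5, 39.5, by = 1)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    q <- (65 - lo[i]) / (hi[i] - lo[i])
    # dB per Cam at the 65-dB point, from dB per octave
    cam_fe <- cam_from_hz(fe[i])
    pick <- NULL
    best <- NULL
    for (delta in seq(2.5, 0.8, by = -0.1)) {
      c65 <- cam_fe + delta
      f65 <- hz_from_cam(c65)
      cams_per_oct <- cam_from_hz(2 * f65) - cam_from_hz(f65)
      db_per_cam <- slope_oct[i] / cams_per_oct
      k <- db_per_cam / ((hi[i] - lo[i]) * q * (1 - q))
      c0 <- c65 - stats::qlogis(q) / k
      hl_fe <- lo[i] + (hi[i] - lo[i]) * stats::plogis(k * (cam_fe - c0))
      pu <- 4 * fe[i] / erb_n_hz(fe[i])
      e_sig <- 75 + 10 * log10(roex_w((f65 - fe[i]) / fe[i], pu))
      margin <- e_sig - hl_fe
      cand <- list(delta = delta, k = k, c0 = c0, margin = margin)
      if (is.null(best) || margin > best$margin) best <- cand
      if (margin >= 3) { pick <- cand; break }
    }
    if (is.null(pick)) pick <- best
    hl <- lo[i] + (hi[i] - lo[i]) * stats::plogis(pick$k * (cam_pts - pick$c0))
    a <- audiogram(hz_from_cam(cam_pts), pmin(pmax(hl, -10), 120),
                   ear = sprintf("sim-%02d", i))
    hl_fe <- interpolate_hl(a, fe[i])
    ohcl <- stats::runif(1, 10, min(65, hl_fe))
    profiles[[i]] <- listener_profile(
      true_fe_hz = fe[i], true_ohcl = ohcl, audiogram = a,
      psych_sd = psych_sd[i], false_alarm_rate = fa[i],
      label = sprintf("sim-%02d", i))
  }
  profiles
}
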