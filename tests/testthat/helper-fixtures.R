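# Shared fixtures, generated in code and cached for the test run.

.fx <- new.env(parent = emptyenv())

# A deterministic steeply sloping audiogram (no RNG): sigmoidal on the
# Cam axis, rising from ~20 to ~100 dB HL around 15 Cams (~900 Hz).
fx_steep_audiogram <- function() {
  cams <- seq(3, 30, by = 1)
  hl <- 20 + 80 * stats::plogis(1.2 * (cams - 15))
  audiogram(hz_from_cam(cams), hl, ear = "steep fixture")
}

fx_cohort <- function() {
  if (is.null(.fx$cohort)) .fx$cohort <- generate_cohort(seed = 42)
  .fx$cohort
}

fx_profile <- function(i = 4) fx_cohort()[[i]]

# Probe fixed at the 65-dB-HL frequency, 10 dB SL (the tier every
# dead-region profile in the cohort fails).
fx_sig <- function(p) {
  f65 <- find_freq_at_hl(p$audiogram, 65)
  signal_spec(f65, interpolate_hl(p$audiogram, f65) + 10)
}

fx_engine <- function(i = 4) {
  key <- paste0("eng", i)
  if (is.null(.fx[[key]])) {
    p <- fx_profile(i)
    .fx[[key]] <- build_engine(p$audiogram, fx_sig(p), session_config())
  }
  .fx[[key]]
}

fx_session <- function(i = 4, seed = 11, cfg = NULL) {
  key <- sprintf("ses%d_%d_%s", i, seed, is.null(cfg))
  if (is.null(.fx[[key]])) {
    p <- fx_profile(i)
    sig <- fx_sig(p)
    if (is.null(cfg)) cfg <- session_config(rng_seed = seed)
    .fx[[key]] <- run_session(cfg, make_responder(p, sig), p$audiogram,
                              sig, engine = fx_engine(i))
  }
  .fx[[key]]
}

# Eligible recovery subset: typical slope (3 dB) and 1% false alarms.
fx_eligible_idx <- function() {
  which(vapply(fx_cohort(), function(p)
    p$psych_sd == 3 && p$false_alarm_rate == 0.01, logical(1)))
}
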