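# Excitation-pattern hearing model.
#
# Detection of the probe tone is evaluated at a single place: the auditory
# filter centred on the candidate edge frequency f_e. The filter is a
# rounded-exponential (roex) weighting W(g) = (1 + p|g|) exp(-p|g|) with
# g = (f - cf)/cf. The upper (high-frequency) skirt keeps the normal
# sharpness; the lower skirt broadens with masker level above 51 dB and
# with outer-hair-cell loss, which is what makes tuning-curve shape
# informative about OHCL.

# Normal-sharpness slope of the 1-kHz filter, reference for the level term.
P51_REF <- 4 * 1000 / (24.7 * (4.37 + 1))

# Cap on OHCL: filter broadening saturates beyond this.
OHCL_CAP <- 65

#' Roex filter weighting
#'
#' W(g) = (1 + p|g|) exp(-p|g|) with g the normalised frequency deviation
#' (f - cf)/cf. Larger p means sharper tuning.
#'
#' @param g Normalised deviation (vectorised).
#' @param p Slope parameter (> 0).
#' @return Power weighting in \[0, 1\].
#' @export
roex_w <- function(g, p) {
  u <- p * abs(g)
  (1 + u) * exp(-u)
}

#' Roex filter slopes for a given place, context level and OHC loss
#'
#' The upper skirt is fixed at the normal value p51 = 4 cf / ERB_N(cf).
#' The lower skirt is p51 scaled by max(0.2, 1 - ohcl/65) and reduced by
#' 0.35 (p51 / p51_at_1kHz) dB^-1 per dB of input level above 51 dB,
#' floored at 0.2 p51. The context level is the masker overall level, the
#' dominant component of the input.
#'
#' @param cf Centre frequency (Hz).
#' @param input_level Context level in dB HL, within \[0, 110\].
#' @param ohcl Outer-hair-cell loss in dB (>= 0; values above 65 are
#'   clipped with a warning).
#' @param broadening Multiplier on the OHCL broadening coefficient; 1 for
#'   the inference model, perturbed to probe model mismatch.
#' @return A list of class `"roex_shape"` with `cf`, `p_lower`, `p_upper`.
#' @export
#' @examples
#' filter_slopes(1000, 51, 0)  # p_lower = p_upper ~ 30.16
filter_slopes <- function(cf, input_level, ohcl, broadening = 1) {
  if (any(ohcl < 0)) stop("ohcl must be non-negative")
  if (any(input_level < 0 | input_level > 110))
    stop("input_level must lie within [0, 110] dB")
  if (any(ohcl > OHCL_CAP)) {
    warning("ohcl above cap of ", OHCL_CAP, " dB; clipped")
    ohcl <- pmin(ohcl, OHCL_CAP)
  }
  p51 <- 4 * cf / erb_n_hz(cf)
  broad <- pmax(0.2, 1 - broadening * ohcl / OHCL_CAP)
  p_lower <- p51 * broad - 0.35 * (p51 / P51_REF) * pmax(0, input_level - 51)
  p_lower <- pmax(p_lower, 0.2 * p51)
  structure(list(cf = cf, p_lower = p_lower, p_upper = p51),
            class = "roex_shape")
}

#' Excitation level of a pure tone at the filter place
#'
#' E = l_tone + 10 log10(W(g)); on-frequency tones excite at exactly their
#' level (0-dB tip gain convention), so excitation levels share the dB HL
#' reference and are directly comparable to audiometric thresholds.
#'
#' @param shape A `"roex_shape"`.
#' @param f_tone Tone frequency (Hz).
#' @param l_tone Tone level (dB HL).
#' @return Excitation level in dB.
#' @export
excitation_tone <- function(shape, f_tone, l_tone) {
  g <- (f_tone - shape$cf) / shape$cf
  p <- ifelse(f_tone < shape$cf, shape$p_lower, shape$p_upper)
  l_tone + 10 * log10(roex_w(g, p))
}

# Exact band integral of W over [lo, hi] for a filter at cf with slopes
# pl (below cf) and pu (above cf). Uses the antiderivative of
# (1+u)exp(-u), which is -(2+u)exp(-u). All arguments vectorised.
.roex_band_integral <- function(cf, pl, pu, lo, hi) {
  # lower-side segment [lo, min(hi, cf)]
  b <- pmin(hi, cf)
  ua <- pl * (cf - lo) / cf
  ub <- pl * (cf - b) / cf
  i_low <- (cf / pl) * ((2 + ub) * exp(-ub) - (2 + ua) * exp(-ua))
  i_low <- ifelse(lo < cf, i_low, 0)
  # upper-side segment [max(lo, cf), hi]
  a <- pmax(lo, cf)
  ua <- pu * (a - cf) / cf
  ub <- pu * (hi - cf) / cf
  i_up <- (cf / pu) * ((2 + ua) * exp(-ua) - (2 + ub) * exp(-ub))
  i_up <- ifelse(hi > cf, i_up, 0)
  i_low + i_up
}

# Excitation of a broadband threshold-equalizing noise specified in
# dB HL/ERB_N. The spectrum level is approximated as locally flat at the
# value it takes near cf; for a normal filter this reduces to E = level.
.ten_excitation <- function(cf, pl, pu, level) {
  i_low <- (cf / pl) * (2 - (2 + pl) * exp(-pl))
  i_up <- 2 * cf / pu
  level - 10 * log10(erb_n_hz(cf)) + 10 * log10(i_low + i_up)
}

#' Excitation level of broadband threshold-equalizing noise
#'
#' @param shape A `"roex_shape"`.
#' @param level TEN level in dB HL/ERB_N.
#' @return Excitation level in dB at the filter place.
#' @export
ten_excitation <- function(shape, level) {
  .ten_excitation(shape$cf, shape$p_lower, shape$p_upper, level)
}

#' Excitation level of a narrowband masking noise
#'
#' The noise band is centred on `f_mask` with bandwidth
#' max(ERB_N(f_mask), 200 Hz), flat spectrum, total level `l_mask`. The
#' excitation is l_mask + 10 log10(mean of W over the band), computed with
#' the exact roex band integral. Bands reaching below 20 Hz are truncated
#' there and the spectrum renormalised over the remaining width. An
#' optional broadband TEN background (dB HL/ERB_N) is added in intensity.
#'
#' @param shape A `"roex_shape"`.
#' @param f_mask Masker centre frequency (Hz).
#' @param l_mask Masker overall level (dB HL).
#' @param ten_floor Background TEN level in dB HL/ERB_N, or `NULL` for
#'   none.
#' @param bandwidth Override the bandwidth rule (Hz); used to study the
#'   narrowband limit.
#' @return Excitation level in dB.
#' @export
excitation_noise <- function(shape, f_mask, l_mask, ten_floor = NULL,
                             bandwidth = NULL) {
  b <- if (is.null(bandwidth)) max(erb_n_hz(f_mask), 200) else bandwidth
  lo <- pmax(20, f_mask - b / 2)
  hi <- f_mask + b / 2
  int <- .roex_band_integral(shape$cf, shape$p_lower, shape$p_upper, lo, hi)
  e <- l_mask + 10 * log10(int / (hi - lo))
  if (!is.null(ten_floor)) {
    e_floor <- ten_excitation(shape, ten_floor)
    e <- 10 * log10(10^(e / 10) + 10^(e_floor / 10))
  }
  e
}

# Core of the detection model, vectorised over candidate cells.
# Returns E_sig - max(E_noise, HL_total(f_e)) for one stimulus, where all
# excitation is evaluated at cf = f_e and the filter's level-dependent
# slope is set by the masker overall level.
.cell_excitation_diff <- function(fe_hz, ohcl, hl_fe, f_mask, l_mask, sig,
                                  ten_floor = 35, broadening = 1) {
  pu <- 4 * fe_hz / erb_n_hz(fe_hz)
  broad <- pmax(0.2, 1 - broadening * pmin(ohcl, OHCL_CAP) / OHCL_CAP)
  pl <- pmax(0.2 * pu,
             pu * broad - 0.35 * (pu / P51_REF) * max(0, l_mask - 51))
  g_sig <- (sig$f_sig - fe_hz) / fe_hz
  p_sig <- ifelse(sig$f_sig < fe_hz, pl, pu)
  e_sig <- sig$l_sig + 10 * log10(roex_w(g_sig, p_sig))
  b <- max(erb_n_hz(f_mask), 200)
  lo <- max(20, f_mask - b / 2)
  hi <- f_mask + b / 2
  int <- .roex_band_integral(fe_hz, pl, pu, lo, hi)
  e_noise <- l_mask + 10 * log10(int / (hi - lo))
  if (!is.null(ten_floor)) {
    e_floor <- .ten_excitation(fe_hz, pl, pu, ten_floor)
    e_noise <- 10 * log10(10^(e_noise / 10) + 10^(e_floor / 10))
  }
  e_sig - pmax(e_noise, hl_fe)
}

#' Probability of a hit (yes response on a signal trial)
#'
#' The detection likelihood: a Gaussian CDF of the difference between the
#' signal excitation and the effective masker excitation at the place f_e,
#' scaled into \[lapse, 1 - lapse\]. The effective masker excitation is
#' max(E_noise, HL_total(f_e)) because the threshold in quiet can limit
#' audibility. With the defaults (sd 3 dB, lapse 0.01) the probability is
#' exactly 0.5 when the excitations are equal and spans \[0.01, 0.99\].
#'
#' @param x A `"stimulus"` (masker frequency and level).
#' @param theta Model parameters: list with `fe_hz` (edge frequency, Hz)
#'   and `ohcl` (outer-hair-cell loss at f_e, dB).
#' @param sig A `"signal_spec"`.
#' @param a An `"audiogram"`.
#' @param sd Psychometric slope parameter in dB (> 0).
#' @param lapse Lapse rate, in \[0, 0.5).
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @return Hit probability.
#' @export
hit_probability <- function(x, theta, sig, a, sd = 3, lapse = 0.01,
                            ten_floor = 35) {
  stopifnot(sd > 0, lapse >= 0, lapse < 0.5)
  if (theta$fe_hz >= sig$f_sig)
    stop("theta: f_e must lie below the signal frequency")
  hl_fe <- interpolate_hl(a, theta$fe_hz)
  if (theta$ohcl < 0 || theta$ohcl > hl_fe + 1e-9)
    stop("theta: ohcl must lie within [0, HL_total(f_e)]")
  d <- .cell_excitation_diff(theta$fe_hz, theta$ohcl, hl_fe,
                             x$f_mask, x$l_mask, sig, ten_floor)
  lapse + (1 - 2 * lapse) * stats::pnorm(d / sd)
}

#' Predicted psychophysical tuning curve
#'
#' For each masker frequency, the masker level at which the hit
#' probability is 0.5 (signal excitation equals effective masker
#' excitation), found by monotone root-finding over the level bounds.
#' Points where no level within bounds reaches the criterion are `NA`. If
#' the 10-dB-SL signal would already be inaudible in quiet under `theta`
#' (E_sig at f_e below HL_total(f_e)), all points are `NA` and the result
#' carries attribute `inaudible = TRUE`.
#'
#' @param theta List with `fe_hz` and `ohcl`.
#' @param sig A `"signal_spec"`.
#' @param a An `"audiogram"`.
#' @param f_mask_grid Masker frequencies (Hz).
#' @param level_bounds Masker level search range, dB HL.
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @return Numeric vector of masker levels (dB HL), `NA` where undefined.
#' @export
predict_ptc <- function(theta, sig, a, f_mask_grid,
                        level_bounds = c(20, 90), ten_floor = 35) {
  stopifnot(all(f_mask_grid > 0))
  hl_fe <- interpolate_hl(a, theta$fe_hz)
  pu <- 4 * theta$fe_hz / erb_n_hz(theta$fe_hz)
  g_sig <- (sig$f_sig - theta$fe_hz) / theta$fe_hz
  e_sig <- sig$l_sig + 10 * log10(roex_w(g_sig, pu))
  out <- rep(NA_real_, length(f_mask_grid))
  if (e_sig < hl_fe) {
    attr(out, "inaudible") <- TRUE
    return(out)
  }
  for (i in seq_along(f_mask_grid)) {
    fm <- f_mask_grid[i]
    h <- function(l) .cell_excitation_diff(theta$fe_hz, theta$ohcl, hl_fe,
                                           fm, l, sig, ten_floor)
    d_lo <- h(level_bounds[1])
    d_hi <- h(level_bounds[2])
    if (d_lo < 0 || d_hi > 0) next  # criterion unreachable within bounds
    out[i] <- stats::uniroot(h, interval = level_bounds, tol = 1e-9)$root
  }
  attr(out, "inaudible") <- FALSE
  out
}
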