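# Post-hoc reliability analyses: false-alarm rate, psychometric-slope
# estimation with iterative outlier rejection, and convergence
# diagnostics over the trial sequence.

#' False-alarm rate over the catch trials
#'
#' @param trials A session trial log (data frame with `is_catch` and
#'   `response`).
#' @return Proportion of yes responses on catch trials.
#' @export
false_alarm_rate <- function(trials) {
  ct <- trials$is_catch
  if (!any(ct)) stop("no catch trials in the log")
  mean(trials$response[ct])
}

#' Express masker levels relative to the fitted tuning curve
#'
#' Removes the effect of masker frequency by subtracting, from each
#' inference trial's masker level, the 50%-point level predicted at that
#' frequency from the MAP parameters. Catch and practice trials are
#' excluded; trials whose predicted level is undefined are dropped with a
#' warning.
#'
#' @param trials A session trial log.
#' @param theta_map MAP parameters: list with `fe_hz`, `ohcl`.
#' @param sig A `"signal_spec"`.
#' @param a An `"audiogram"`.
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @param level_bounds Tuning-curve search bounds, dB HL.
#' @return Data frame with `rel_level` (dB) and `response` (logical).
#' @export
normalize_levels <- function(trials, theta_map, sig, a, ten_floor = 35,
                             level_bounds = c(20, 90)) {
  keep <- !trials$is_catch & trials$phase != "practice" &
    !is.na(trials$response)
  t2 <- trials[keep, , drop = FALSE]
  if (nrow(t2) == 0) stop("no inference trials in the log")
  fm <- sort(unique(t2$f_mask_hz))
  ptc <- predict_ptc(theta_map, sig, a, fm, level_bounds = level_bounds,
                     ten_floor = ten_floor)
  ref <- ptc[match(t2$f_mask_hz, fm)]
  drop <- is.na(ref)
  if (any(drop))
    warning(sum(drop), " trial(s) dropped: tuning curve undefined at ",
            "their masker frequency")
  data.frame(rel_level = t2$l_mask_db_hl[drop == FALSE] - ref[!drop],
             response = t2$response[!drop])
}

# Penalised-ML probit fit of the psychometric function in relative level.
# P(yes | L) = lapse + (1 - 2 lapse) * Phi(-(L - m)/s); a weak ridge on m
# keeps the location identified under sparse designs. Returns c(m, s).
.fit_probit <- function(L, y, lapse = 0.01, s_bounds = c(0.02, 200)) {
  nll <- function(par) {
    m <- par[1]
    s <- exp(par[2])
    p <- lapse + (1 - 2 * lapse) * stats::pnorm(-(L - m) / s)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p)) + (m / 30)^2 / 2
  }
  fit <- stats::optim(c(0, log(3)), nll, method = "L-BFGS-B",
                      lower = c(-60, log(s_bounds[1])),
                      upper = c(60, log(s_bounds[2])))
  c(m = fit$par[1], s = exp(fit$par[2]))
}

#' Estimate the psychometric slope with iterative outlier rejection
#'
#' Fits a probit response curve (Gaussian-CDF link, latent linear in
#' relative masker level) to normalised yes/no data. Yes responses at
#' relative levels above +3 current-sd and no responses below -3
#' current-sd are treated as outliers; the outlier set is recomputed from
#' the full data and the model refitted until stable (at most `max_iter`
#' passes, first pass at sd = 3 dB). Perfectly separated data (all yes
#' below all no with a gap) drive the estimate toward zero and set the
#' `separable` flag; an estimate above about 20 dB indicates responses
#' unrelated to level (a restart is advisable).
#'
#' @param normalized Data frame from [normalize_levels()] with
#'   `rel_level` and `response`.
#' @param lapse Lapse rate in the fitted curve.
#' @param max_iter Maximum outlier-rejection passes.
#' @param min_points Fewer usable points than this flags the estimate.
#' @return List with `sd` (dB), `separable`, `n_outliers`, `n_used`,
#'   `flagged`.
#' @export
estimate_slope <- function(normalized, lapse = 0.01, max_iter = 10,
                           min_points = 10) {
  L <- normalized$rel_level
  y <- as.logical(normalized$response)
  if (length(L) < min_points)
    return(list(sd = NA_real_, separable = NA, n_outliers = 0L,
                n_used = length(L), flagged = TRUE))
  if (all(y) || all(!y))
    return(list(sd = NA_real_, separable = NA, n_outliers = 0L,
                n_used = length(L), flagged = TRUE))
  sd_cur <- 3
  keep <- rep(TRUE, length(L))
  for (it in seq_len(max_iter)) {
    keep_new <- !((y & L > 3 * sd_cur) | (!y & L < -3 * sd_cur))
    if (sum(keep_new) < 2 || all(y[keep_new]) || all(!y[keep_new]))
      keep_new <- keep  # rejection degenerate; stop with current set
    fit <- .fit_probit(L[keep_new], y[keep_new], lapse)
    sd_cur <- fit[["s"]]
    if (identical(keep_new, keep) && it > 1) break
    keep <- keep_new
  }
  separable <- max(L[y]) < min(L[!y]) || sd_cur < 0.3
  list(sd = sd_cur, separable = separable,
       n_outliers = sum(!keep), n_used = sum(keep),
       flagged = sum(keep) < min_points)
}

#' Convergence diagnostics over the trial sequence
#'
#' For every prefix of the inference trials, recomputes the posterior
#' from the cached per-trial likelihoods and reports: `nlp`, the mean
#' negative (natural) log posterior-predictive probability of all
#' observed inference responses given the first N trials; `ratio`, the
#' edge-frequency estimate after N trials relative to the final estimate
#' (folded to be >= 1, on the Hz scale); and `mi`, the information
#' queried on trial N (NA for initial-grid trials).
#'
#' @param session A `"drt_session"`.
#' @return Data frame with one row per N = 0..(number of inference
#'   trials): `n_trials`, `nlp`, `ratio`, `mi_bits`.
#' @export
session_diagnostics <- function(session) {
  stopifnot(inherits(session, "drt_session"))
  ll <- session$loglik
  n <- ncol(ll)
  lik <- exp(ll)
  lp0 <- log(session$prior_prob)
  cum <- cbind(0, t(apply(ll, 1, cumsum)))
  w <- lp0 + cum                       # cells x (n + 1) log posteriors
  w <- exp(sweep(w, 2, apply(w, 2, max)))
  w <- sweep(w, 2, colSums(w), "/")
  pred <- crossprod(lik, w)            # trials x (n + 1) predictive probs
  nlp <- -colMeans(log(pred))
  g <- session$grid
  fe_hat <- vapply(seq_len(n + 1), function(j) {
    m <- rowsum(w[, j], g$cells_fe)
    g$fe_hz[as.integer(rownames(m))[which.max(m)]]
  }, numeric(1))
  r <- fe_hat / fe_hat[n + 1]
  data.frame(n_trials = 0:n, nlp = nlp, ratio = pmax(r, 1 / r),
             mi_bits = c(NA_real_, session$mi_trace))
}
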