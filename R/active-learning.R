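# Active-learning stimulus selection and session orchestration.
#
# Each trial's masker is drawn with probability proportional to the mutual
# information between the next response and the model parameters (a BALD
# score: predictive entropy minus expected conditional entropy), weighted
# by a Gaussian in Cam distance from the current f_e estimate, with
# candidates within 2 Cams of the previous masker excluded.

#' Session configuration
#'
#' Defaults encode the standard protocol: 100 inference trials (16 initial
#' grid + 84 actively selected), 20 catch trials randomly interleaved, 4
#' practice trials, a 3-dB psychometric slope with 1% lapse rate, 1.5-Cam
#' selection weighting and a 2-Cam repeat-exclusion radius.
#'
#' @param n_active_trials Number of inference (non-catch) trials,
#'   including the 16-trial initial grid.
#' @param n_catch Number of catch trials (at most `n_active_trials / 2`).
#' @param n_practice Number of practice trials (excluded from inference).
#' @param sd Psychometric slope parameter in dB.
#' @param lapse Lapse rate.
#' @param weight_sigma Gaussian selection-weight sd in Cams.
#' @param exclusion_radius Repeat-exclusion radius in Cams.
#' @param rng_seed Integer seed; the session consumes a single RNG stream.
#' @param adaptive_sd Re-estimate the slope during the run: 3 dB for the
#'   first 10 actively selected trials, afterwards the running estimate
#'   floored at `sd_floor`; values above `sd_restart` flag a restart.
#' @param sd_floor,sd_restart Adaptive-slope floor and restart threshold
#'   (dB).
#' @param early_stop Stop once the queried information has stayed below
#'   `stop_mi_threshold` for 3 consecutive active trials.
#' @param stop_mi_threshold Stopping threshold in bits.
#' @param ten_floor Background TEN level in dB HL/ERB_N (or `NULL`).
#' @return A list of class `"drt_config"`.
#' @export
session_config <- function(n_active_trials = 100, n_catch = 20,
                           n_practice = 4, sd = 3, lapse = 0.01,
                           weight_sigma = 1.5, exclusion_radius = 2,
                           rng_seed = 1, adaptive_sd = FALSE,
                           sd_floor = 2, sd_restart = 20,
                           early_stop = FALSE, stop_mi_threshold = 0.1,
                           ten_floor = 35) {
  stopifnot(n_active_trials >= 16, n_catch >= 0, sd > 0,
            lapse >= 0, lapse < 0.5, weight_sigma > 0,
            exclusion_radius >= 0)
  if (n_catch > n_active_trials / 2)
    stop("n_catch must not exceed n_active_trials / 2")
  structure(list(n_active_trials = n_active_trials, n_catch = n_catch,
                 n_practice = n_practice, sd = sd, lapse = lapse,
                 weight_sigma = weight_sigma,
                 exclusion_radius = exclusion_radius,
                 rng_seed = as.integer(rng_seed),
                 adaptive_sd = adaptive_sd, sd_floor = sd_floor,
                 sd_restart = sd_restart, early_stop = early_stop,
                 stop_mi_threshold = stop_mi_threshold,
                 ten_floor = ten_floor),
            class = "drt_config")
}

#' Candidate stimulus lattice
#'
#' Masker frequencies on a 0.25-Cam lattice over the 8 Cams up to the
#' probe frequency, crossed with levels from 20 to 90 dB HL in 2-dB steps.
#'
#' @param sig A `"signal_spec"`.
#' @param fe_span_cam Lattice span below the probe, Cams.
#' @param f_step_cam Frequency step in Cams.
#' @param level_range,level_step Level lattice bounds and step (dB HL).
#' @return Data frame with `f_mask_hz`, `f_mask_cam`, `l_mask`.
#' @export
candidate_grid <- function(sig, fe_span_cam = 8, f_step_cam = 0.25,
                           level_range = c(20, 90), level_step = 2) {
  cam_sig <- cam_from_hz(sig$f_sig)
  cams <- seq(cam_sig - fe_span_cam, cam_sig, by = f_step_cam)
  levels <- seq(level_range[1], level_range[2], by = level_step)
  d <- expand.grid(f_mask_cam = cams, l_mask = levels,
                   KEEP.OUT.ATTRS = FALSE)
  d$f_mask_hz <- hz_from_cam(d$f_mask_cam)
  d[, c("f_mask_hz", "f_mask_cam", "l_mask")]
}

#' The fixed 16-trial initial grid
#'
#' Eight maskers 2 Cams below the probe at levels of -20, -9, -6, -3, 0,
#' 3, 6 and 9 dB relative to the probe level (ascending), then the same
#' eight levels with the masker 4 Cams below the probe. Levels outside the
#' bounds are clipped and flagged via attribute `clipped`.
#'
#' @param sig A `"signal_spec"`.
#' @param level_bounds Allowed masker level range, dB HL.
#' @return Data frame of 16 rows: `f_mask_hz`, `f_mask_cam`, `l_mask`.
#' @export
initial_grid <- function(sig, level_bounds = c(20, 90)) {
  offsets <- c(-20, -9, -6, -3, 0, 3, 6, 9)
  cam_sig <- cam_from_hz(sig$f_sig)
  d <- data.frame(
    f_mask_cam = rep(cam_sig - c(2, 4), each = length(offsets)),
    l_mask = rep(sig$l_sig + offsets, times = 2))
  d$f_mask_hz <- hz_from_cam(d$f_mask_cam)
  clipped <- d$l_mask < level_bounds[1] | d$l_mask > level_bounds[2]
  if (any(clipped)) {
    warning(sum(clipped), " initial-grid level(s) clipped to bounds")
    d$l_mask <- pmin(pmax(d$l_mask, level_bounds[1]), level_bounds[2])
  }
  d <- d[, c("f_mask_hz", "f_mask_cam", "l_mask")]
  attr(d, "clipped") <- any(clipped)
  d
}

#' Binary entropy in bits
#'
#' @param p Probability (vectorised).
#' @return Entropy in bits; 0 at p = 0 or 1.
#' @export
binary_entropy <- function(p) {
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -p[nz] * log2(p[nz]) - (1 - p[nz]) * log2(1 - p[nz])
  h
}

#' Mutual information between the next response and the parameters
#'
#' I(y*; theta | x*) = Hb(p_bar) minus the posterior expectation of
#' Hb(p_theta), where p_theta is
#' the hit probability under each cell and p_bar the posterior-predictive
#' hit probability. Bounded by 1 bit for a binary response.
#'
#' @param post A `"drt_posterior"`.
#' @param x_star Candidate stimulus: list with `f_mask`, `l_mask`.
#' @param sig A `"signal_spec"`.
#' @param a The `"audiogram"`.
#' @param sd,lapse,ten_floor Likelihood parameters.
#' @return Expected information gain in bits.
#' @export
mutual_information <- function(post, x_star, sig, a, sd = 3, lapse = 0.01,
                               ten_floor = 35) {
  idx <- post$grid$cells_idx
  pc <- post$prob[idx]
  p_th <- .cell_likelihood(post, x_star, TRUE, sig, sd, lapse, ten_floor)
  pbar <- sum(pc * p_th)
  max(0, binary_entropy(pbar) - sum(pc * binary_entropy(p_th)))
}

#' Precompute the session engine
#'
#' Evaluates the excitation difference for every admissible cell at every
#' candidate stimulus once, so that per-trial likelihoods and the mutual
#' information over the whole candidate lattice reduce to matrix products.
#' Reusable across sessions that share an audiogram and probe.
#'
#' @param a An `"audiogram"`.
#' @param sig A `"signal_spec"`.
#' @param cfg A `"drt_config"`.
#' @return A list of class `"drt_engine"`.
#' @export
build_engine <- function(a, sig, cfg = session_config()) {
  prior <- build_prior(a, sig)
  g <- prior$grid
  cand <- candidate_grid(sig)
  fe <- g$fe_hz[g$cells_fe]
  oh <- g$ohcl_db[g$cells_ohcl]
  hl <- g$hl_fe[g$cells_fe]
  d <- matrix(NA_real_, length(fe), nrow(cand))
  for (k in seq_len(nrow(cand))) {
    d[, k] <- .cell_excitation_diff(fe, oh, hl, cand$f_mask_hz[k],
                                    cand$l_mask[k], sig, cfg$ten_floor)
  }
  eng <- list(prior = prior, cand = cand, D = d, audiogram = a, sig = sig,
              cfg = cfg, sd = NULL, lapse = cfg$lapse)
  eng <- engine_set_sd(eng, cfg$sd, cfg$lapse)
  class(eng) <- "drt_engine"
  eng
}

#' Re-scale the engine's precomputed likelihoods for a new slope
#'
#' @param engine A `"drt_engine"`.
#' @param sd New psychometric slope (dB).
#' @param lapse Lapse rate.
#' @return The engine with refreshed probability matrices.
#' @export
engine_set_sd <- function(engine, sd, lapse = engine$lapse) {
  p <- lapse + (1 - 2 * lapse) * stats::pnorm(engine$D / sd)
  engine$P <- p
  engine$HbP <- matrix(binary_entropy(p), nrow(p), ncol(p))
  engine$sd <- sd
  engine$lapse <- lapse
  engine
}

# Mutual information for every candidate at once (engine fast path).
.engine_mi <- function(engine, pc) {
  pbar <- as.vector(crossprod(engine$P, pc))
  eh <- as.vector(crossprod(engine$HbP, pc))
  pmax(0, binary_entropy(pbar) - eh)
}

#' Draw the next stimulus
#'
#' Sampling probability is proportional to the candidate's mutual
#' information times a Gaussian weight (sd `weight_sigma` Cams) centred on
#' the current f_e estimate; candidates within `exclusion_radius` Cams of
#' the previous masker get zero weight. If every weight vanishes the draw
#' falls back to uniform over the non-excluded candidates (flagged).
#'
#' @param post A `"drt_posterior"`.
#' @param cand Candidate lattice from [candidate_grid()].
#' @param fe_hat Current MAP edge frequency in Cams.
#' @param prev_f_mask Previous trial's masker frequency in Hz (`NA` for
#'   none).
#' @param sig,a,sd,lapse,ten_floor Passed to [mutual_information()] when
#'   `mi` is not supplied.
#' @param mi Optional precomputed per-candidate information (bits).
#' @param weight_sigma Gaussian weight sd in Cams.
#' @param exclusion_radius Exclusion radius in Cams.
#' @return List with `f_mask`, `l_mask`, `index`, `mi_bits`, `fallback`.
#' @export
select_next_stimulus <- function(post, cand, fe_hat, prev_f_mask,
                                 sig = NULL, a = NULL, sd = 3,
                                 lapse = 0.01, ten_floor = 35, mi = NULL,
                                 weight_sigma = 1.5, exclusion_radius = 2) {
  if (is.null(mi)) {
    mi <- vapply(seq_len(nrow(cand)), function(k) {
      mutual_information(post,
                         list(f_mask = cand$f_mask_hz[k],
                              l_mask = cand$l_mask[k]),
                         sig, a, sd, lapse, ten_floor)
    }, numeric(1))
  }
  w <- mi * stats::dnorm(cand$f_mask_cam, fe_hat, weight_sigma)
  excl <- if (is.na(prev_f_mask)) rep(FALSE, nrow(cand)) else
    abs(cand$f_mask_cam - cam_from_hz(prev_f_mask)) < exclusion_radius
  w[excl] <- 0
  fallback <- FALSE
  if (!any(w > 0)) {
    fallback <- TRUE
    w <- as.numeric(!excl)
    if (!any(w > 0)) stop("no candidate outside the exclusion zone")
  }
  i <- sample.int(length(w), 1L, prob = w)
  list(f_mask = cand$f_mask_hz[i], l_mask = cand$l_mask[i], index = i,
       mi_bits = mi[i], fallback = fallback)
}

#' Information-based stopping rule
#'
#' TRUE once the last three entries of the queried-information trace are
#' all below the threshold; three in a row guards against stopping on one
#' uninformative trial.
#'
#' @param mi_trace Queried information per active trial (bits); `NA`
#'   entries (initial-grid trials) are ignored.
#' @param threshold Threshold in bits.
#' @return Logical.
#' @export
stopping_check <- function(mi_trace, threshold = 0.1) {
  mi <- mi_trace[!is.na(mi_trace)]
  if (length(mi) < 3) return(FALSE)
  all(utils::tail(mi, 3) < threshold)
}

#' Run a complete adaptive session
#'
#' Presents 4 practice trials (fixed easy stimuli, excluded from
#' inference), the 16-trial initial grid, then actively selected trials,
#' with catch trials interleaved at positions drawn once at session start
#' among all post-practice trials. The posterior is updated after every
#' non-catch, non-practice trial; the MAP edge frequency and the queried
#' information are recorded per trial. The final estimate is the MAP of
#' the last posterior.
#'
#' @param cfg A `"drt_config"`.
#' @param responder Function `(x, is_catch)` returning a logical yes/no,
#'   where `x` is a list with `f_mask` and `l_mask`. See
#'   [make_responder()].
#' @param a An `"audiogram"`.
#' @param sig A `"signal_spec"`.
#' @param engine Optional precomputed [build_engine()] result for this
#'   audiogram/probe (built on the fly otherwise).
#' @return A list of class `"drt_session"`: the trial log, posterior,
#'   per-trial traces, final estimate, flags, and the cached per-trial
#'   likelihoods needed by [session_diagnostics()].
#' @export
run_session <- function(cfg, responder, a, sig, engine = NULL) {
  stopifnot(inherits(cfg, "drt_config"))
  set.seed(cfg$rng_seed)
  rngc <- 0L
  if (is.null(engine)) engine <- build_engine(a, sig, cfg)
  if (!identical(engine$sd, cfg$sd) || !identical(engine$lapse, cfg$lapse))
    engine <- engine_set_sd(engine, cfg$sd, cfg$lapse)
  prior <- engine$prior
  g <- prior$grid
  idx <- g$cells_idx
  pc <- prior$prob[idx]
  lp <- log(pc)
  n_inf <- cfg$n_active_trials
  n_catch <- cfg$n_catch
  total <- n_inf + n_catch
  catch_pos <- if (n_catch > 0) sort(sample.int(total, n_catch)) else integer(0)
  rngc <- rngc + 1L
  grid16 <- initial_grid(sig)
  cand <- engine$cand
  flags <- character(0)
  if (isTRUE(attr(grid16, "clipped"))) flags <- c(flags, "grid_levels_clipped")

  nrows <- cfg$n_practice + total
  rec <- data.frame(index = seq_len(nrows), phase = NA_character_,
                    f_mask_hz = NA_real_, l_mask_db_hl = NA_real_,
                    is_catch = FALSE, response = NA,
                    mi_bits = NA_real_, fe_map_cam = NA_real_,
                    posterior_entropy_bits = NA_real_,
                    rng_call_count = NA_integer_, sd_db = NA_real_,
                    stringsAsFactors = FALSE)
  loglik <- matrix(NA_real_, length(idx), n_inf)
  fe_map_trace <- rep(NA_real_, n_inf)
  mi_trace <- rep(NA_real_, n_inf)
  sd_trace <- rep(NA_real_, n_inf)
  marg_map <- function(pc) {
    m <- rowsum(pc, g$cells_fe)
    g$fe_cam[as.integer(rownames(m))[which.max(m)]]
  }
  ent_bits <- function(pc) {
    p <- pc[pc > 0]
    -sum(p * log2(p))
  }

  # practice: one weak and one strong masker 3 Cams below the probe,
  # alternated, so the listener hears clearly audible and clearly masked
  # examples before scoring starts
  f_prac <- hz_from_cam(cam_from_hz(sig$f_sig) - 3)
  l_prac <- rep(c(sig$l_sig - 30, min(90, sig$l_sig + 10)),
                length.out = cfg$n_practice)
  row <- 0L
  for (i in seq_len(cfg$n_practice)) {
    row <- row + 1L
    x <- list(f_mask = f_prac, l_mask = l_prac[i])
    y <- responder(x, FALSE)
    rngc <- rngc + 1L
    rec$phase[row] <- "practice"
    rec$f_mask_hz[row] <- x$f_mask
    rec$l_mask_db_hl[row] <- x$l_mask
    rec$response[row] <- y
    rec$rng_call_count[row] <- rngc
  }

  sd_cur <- cfg$sd
  prev_f_mask <- NA_real_
  last_x <- list(f_mask = grid16$f_mask_hz[1], l_mask = grid16$l_mask[1])
  k <- 0L
  stopped <- FALSE
  for (pos in seq_len(total)) {
    is_catch <- pos %in% catch_pos
    phase <- if (k < 16L) "initial_grid" else "active"
    if (is_catch) {
      x <- last_x
      y <- responder(x, TRUE)
      rngc <- rngc + 1L
      row <- row + 1L
      rec$phase[row] <- phase
      rec$f_mask_hz[row] <- x$f_mask
      rec$l_mask_db_hl[row] <- x$l_mask
      rec$is_catch[row] <- TRUE
      rec$response[row] <- y
      rec$rng_call_count[row] <- rngc
      next
    }
    k <- k + 1L
    if (k <= 16L) {
      x <- list(f_mask = grid16$f_mask_hz[k], l_mask = grid16$l_mask[k])
      mi_k <- NA_real_
    } else {
      mi_all <- .engine_mi(engine, pc)
      sel <- select_next_stimulus(NULL, cand, fe_hat = marg_map(pc),
                                  prev_f_mask = prev_f_mask, mi = mi_all,
                                  weight_sigma = cfg$weight_sigma,
                                  exclusion_radius = cfg$exclusion_radius)
      rngc <- rngc + 1L
      if (sel$fallback) flags <- c(flags, sprintf("selection_fallback_trial_%d", k))
      x <- list(f_mask = sel$f_mask, l_mask = sel$l_mask)
      mi_k <- sel$mi_bits
    }
    y <- responder(x, FALSE)
    rngc <- rngc + 1L
    lik <- .cell_likelihood(prior, x, y, sig, sd_cur, cfg$lapse,
                            cfg$ten_floor)
    loglik[, k] <- log(lik)
    lp <- lp + log(lik)
    w <- exp(lp - max(lp))
    pc <- w / sum(w)
    fe_map_trace[k] <- marg_map(pc)
    mi_trace[k] <- mi_k
    sd_trace[k] <- sd_cur

    row <- row + 1L
    rec$phase[row] <- if (k <= 16L) "initial_grid" else "active"
    rec$f_mask_hz[row] <- x$f_mask
    rec$l_mask_db_hl[row] <- x$l_mask
    rec$response[row] <- y
    rec$mi_bits[row] <- mi_k
    rec$fe_map_cam[row] <- fe_map_trace[k]
    rec$posterior_entropy_bits[row] <- ent_bits(pc)
    rec$rng_call_count[row] <- rngc
    rec$sd_db[row] <- sd_cur
    prev_f_mask <- x$f_mask
    last_x <- x

    if (cfg$adaptive_sd && k >= 26L && (k - 26L) %% 10L == 0L) {
      est <- .running_slope_estimate(rec[seq_len(row), , drop = FALSE],
                                     prior, pc, sig, a, cfg)
      if (!is.null(est)) {
        if (est > cfg$sd_restart) flags <- c(flags, "restart_recommended")
        sd_new <- max(cfg$sd_floor, min(est, cfg$sd_restart))
        if (abs(sd_new - sd_cur) > 1e-9) {
          sd_cur <- sd_new
          engine <- engine_set_sd(engine, sd_cur, cfg$lapse)
        }
      }
    }
    if (cfg$early_stop && k > 16L &&
        stopping_check(mi_trace[seq_len(k)], cfg$stop_mi_threshold)) {
      flags <- c(flags, "early_stop")
      stopped <- TRUE
      break
    }
  }

  rec <- rec[seq_len(row), , drop = FALSE]
  loglik <- loglik[, seq_len(k), drop = FALSE]
  post <- prior
  post$prob[idx] <- pc
  res <- list(trials = rec, posterior = post, grid = g,
              prior_prob = prior$prob[idx],
              fe_map_trace = fe_map_trace[seq_len(k)],
              mi_trace = mi_trace[seq_len(k)],
              sd_trace = sd_trace[seq_len(k)],
              final_fe_cam = marg_map(pc),
              final_fe_hz = hz_from_cam(marg_map(pc)),
              flags = unique(flags), config = cfg, loglik = loglik,
              sig = sig, audiogram = a, stopped = stopped)
  class(res) <- "drt_session"
  res
}

# Slope re-estimate during a run, from the inference trials so far and the
# current joint MAP. Returns NULL when too few usable points.
.running_slope_estimate <- function(rec, prior, pc, sig, a, cfg) {
  post <- prior
  post$prob[post$grid$cells_idx] <- pc
  th <- map_theta(post)
  norm <- tryCatch(
    suppressWarnings(normalize_levels(rec, th, sig, a,
                                      ten_floor = cfg$ten_floor)),
    error = function(e) NULL)
  if (is.null(norm) || nrow(norm) < 10) return(NULL)
  est <- estimate_slope(norm)
  if (est$flagged) return(NULL)
  est$sd
}

#' @export
print.drt_session <- function(x, ...) {
  cat(sprintf("Adaptive dead-region session: %d trials (%d inference)\n",
              nrow(x$trials), length(x$fe_map_trace)))
  cat(sprintf("  final f_e: %.2f Cams (%.0f Hz)\n",
              x$final_fe_cam, x$final_fe_hz))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
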