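# Discrete-grid Bayesian inference over theta = (f_e, OHCL(f_e)).
#
# The posterior lives on a rectangular grid: edge-frequency bins at
# 0.1-Cam spacing and OHCL bins at 2.5-dB spacing, with an admissibility
# mask imposing the prior constraints. Updates are multiplicative in the
# per-trial likelihood with log-space accumulation.

#' Build the prior over (f_e, OHCL(f_e))
#'
#' Uniform over admissible cells. The f_e support spans the 8 Cams below
#' the signal frequency at 0.1-Cam spacing (cells at or above f_sig are
#' excluded: the edge is known to lie below the probe). OHCL runs from 0
#' to 65 dB at 2.5-dB spacing. A cell is admissible when
#' OHCL <= HL_total(f_e) and the 10-dB-SL probe would be audible in quiet
#' under the cell's parameters (E_sig at f_e >= HL_total(f_e)).
#'
#' @param a An `"audiogram"`; must cover the candidate f_e range.
#' @param sig A `"signal_spec"`.
#' @param fe_span_cam Width of the f_e support below the probe, Cams.
#' @param fe_step f_e bin width in Cams.
#' @param ohcl_max,ohcl_step OHCL grid bounds and spacing (dB).
#' @return An object of class `"drt_posterior"`: a list with `grid`
#'   (bins, admissibility mask and cached model quantities) and `prob`
#'   (matrix of cell probabilities, f_e by OHCL).
#' @export
build_prior <- function(a, sig, fe_span_cam = 8, fe_step = 0.1,
                        ohcl_max = 65, ohcl_step = 2.5) {
  stopifnot(inherits(a, "audiogram"), inherits(sig, "signal_spec"))
  cam_sig <- cam_from_hz(sig$f_sig)
  fe_cam <- seq(cam_sig - fe_span_cam, cam_sig, by = fe_step)
  fe_cam <- fe_cam[fe_cam < cam_sig - 1e-9]
  fe_hz <- hz_from_cam(fe_cam)
  if (min(fe_hz) < min(a$frequency_hz) || max(fe_hz) > max(a$frequency_hz))
    stop(sprintf(paste0("audiogram [%g, %g] Hz does not cover the ",
                        "candidate f_e range [%g, %g] Hz"),
                 min(a$frequency_hz), max(a$frequency_hz),
                 min(fe_hz), max(fe_hz)))
  hl_fe <- interpolate_hl(a, fe_hz)
  pu <- 4 * fe_hz / erb_n_hz(fe_hz)
  e_sig <- sig$l_sig + 10 * log10(roex_w((sig$f_sig - fe_hz) / fe_hz, pu))
  ohcl <- seq(0, ohcl_max, by = ohcl_step)
  nf <- length(fe_cam)
  no <- length(ohcl)
  ohcl_ok <- outer(hl_fe, ohcl, function(h, o) o <= h + 1e-9)
  audible <- e_sig >= hl_fe - 1e-9
  mask <- ohcl_ok & audible
  if (!any(mask)) {
    stop(sprintf(paste0("prior support is empty: %d/%d cells violate ",
                        "OHCL <= HL_total(f_e); %d/%d f_e bins fail the ",
                        "quiet-audibility constraint"),
                 sum(!ohcl_ok), nf * no, sum(!audible), nf))
  }
  idx <- which(mask)
  grid <- list(fe_cam = fe_cam, fe_hz = fe_hz, ohcl_db = ohcl,
               mask = mask, hl_fe = hl_fe, e_sig = e_sig,
               cells_idx = idx,
               cells_fe = row(mask)[idx], cells_ohcl = col(mask)[idx],
               fe_step = fe_step, ohcl_step = ohcl_step, sig = sig)
  prob <- matrix(0, nf, no)
  prob[mask] <- 1 / sum(mask)
  structure(list(grid = grid, prob = prob), class = "drt_posterior")
}

#' @export
print.drt_posterior <- function(x, ...) {
  g <- x$grid
  cat(sprintf(paste0("Posterior over (f_e, OHCL): %d x %d grid, ",
                     "%d admissible cells\n"),
              length(g$fe_cam), length(g$ohcl_db), length(g$cells_idx)))
  cat(sprintf("  f_e support: %.1f-%.1f Cams (%.0f-%.0f Hz)\n",
              min(g$fe_cam), max(g$fe_cam), min(g$fe_hz), max(g$fe_hz)))
  cat(sprintf("  MAP f_e: %.2f Cams (%.0f Hz)\n",
              map_fe(x), hz_from_cam(map_fe(x))))
  invisible(x)
}

# Likelihood of the observed response over the admissible cells.
.cell_likelihood <- function(post, x, y, sig, sd, lapse, ten_floor = 35) {
  g <- post$grid
  d <- .cell_excitation_diff(g$fe_hz[g$cells_fe], g$ohcl_db[g$cells_ohcl],
                             g$hl_fe[g$cells_fe], x$f_mask, x$l_mask,
                             sig, ten_floor)
  p <- lapse + (1 - 2 * lapse) * stats::pnorm(d / sd)
  if (y) p else 1 - p
}

#' One-trial Bayesian update of the posterior
#'
#' Multiplies every admissible cell by the likelihood of the observed
#' response and renormalises, in log space to avoid underflow over long
#' sessions. Catch trials carry no masking-model likelihood and leave the
#' posterior unchanged; practice trials are excluded from inference and
#' are an error here.
#'
#' @param post A `"drt_posterior"`.
#' @param trial A list with `x` (list with `f_mask`, `l_mask`), `y`
#'   (logical response), and optional flags `is_catch`, `is_practice`.
#' @param sig A `"signal_spec"` (must match the prior's).
#' @param a The `"audiogram"` used to build the prior.
#' @param sd Psychometric slope parameter (dB).
#' @param lapse Lapse rate.
#' @param ten_floor Background TEN level (dB HL/ERB_N) or `NULL`.
#' @return The updated `"drt_posterior"`.
#' @export
update_posterior <- function(post, trial, sig, a, sd = 3, lapse = 0.01,
                             ten_floor = 35) {
  stopifnot(inherits(post, "drt_posterior"))
  if (isTRUE(trial$is_practice))
    stop("practice trials are excluded from inference")
  if (isTRUE(trial$is_catch)) return(post)
  idx <- post$grid$cells_idx
  lik <- .cell_likelihood(post, trial$x, trial$y, sig, sd, lapse, ten_floor)
  lp <- log(post$prob[idx]) + log(lik)
  m <- max(lp)
  if (!is.finite(m)) stop("posterior underflow: all cells at zero mass")
  w <- exp(lp - m)
  post$prob[idx] <- w / sum(w)
  post
}

#' Marginal distribution over the edge frequency
#'
#' Sums the joint posterior over the OHCL bins.
#'
#' @param post A `"drt_posterior"`.
#' @return A data frame with `fe_cam`, `fe_hz` and `prob` (sums to 1).
#' @export
marginal_fe <- function(post) {
  data.frame(fe_cam = post$grid$fe_cam, fe_hz = post$grid$fe_hz,
             prob = rowSums(post$prob))
}

#' Maximum a posteriori edge frequency
#'
#' Argmax of the f_e marginal; exact ties break toward the lowest bin.
#'
#' @param post A `"drt_posterior"`.
#' @return Edge-frequency estimate in Cams.
#' @export
map_fe <- function(post) {
  m <- rowSums(post$prob)
  post$grid$fe_cam[which.max(m)]
}

#' Joint MAP parameters
#'
#' @param post A `"drt_posterior"`.
#' @return List with `fe_hz`, `fe_cam`, `ohcl`.
#' @export
map_theta <- function(post) {
  idx <- post$grid$cells_idx
  best <- idx[which.max(post$prob[idx])]
  i <- row(post$grid$mask)[best]
  j <- col(post$grid$mask)[best]
  list(fe_hz = post$grid$fe_hz[i], fe_cam = post$grid$fe_cam[i],
       ohcl = post$grid$ohcl_db[j])
}

#' Shannon entropy of the posterior in bits
#'
#' @param post A `"drt_posterior"`.
#' @return Entropy in bits.
#' @export
posterior_entropy <- function(post) {
  p <- post$prob[post$prob > 0]
  -sum(p * log2(p))
}

#' Export the joint posterior as CSV
#'
#' Columns `fe_cam`, `ohcl_db`, `probability`, one row per grid cell.
#'
#' @param post A `"drt_posterior"`.
#' @param path File path.
#' @export
write_posterior_csv <- function(post, path) {
  g <- post$grid
  d <- expand.grid(fe_cam = g$fe_cam, ohcl_db = g$ohcl_db)
  d$probability <- as.vector(post$prob)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export the f_e marginal as CSV
#'
#' Columns `fe_cam`, `probability`.
#'
#' @param post A `"drt_posterior"`.
#' @param path File path.
#' @export
write_marginal_csv <- function(post, path) {
  m <- marginal_fe(post)
  utils::write.csv(
    data.frame(fe_cam = m$fe_cam, probability = m$prob),
    path, row.names = FALSE)
  invisible(path)
}
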