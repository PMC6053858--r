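# Quick TEN(HL) screening cascade.
#
# Screens the frequencies where the audiogram reaches 65, 70 and 75 dB HL
# for a dead region, and on a positive outcome fixes the probe frequency
# and level (10 dB SL) for the adaptive edge-frequency test.

#' Score one quick TEN(HL) block
#'
#' With 10 signal trials and 10 TEN-only trials, the detectability
#' criterion X >= 1.5 (1 - Y) on the hit proportion X and
#' correct-rejection proportion Y is equivalent to a total of at least 15
#' correct out of 20. Pass means the signal was detectable (no dead region
#' indicated at this frequency); fail indicates one.
#'
#' @param hits Number of hits, 0-10.
#' @param correct_rejections Number of correct rejections, 0-10.
#' @return Logical: `TRUE` for pass.
#' @export
ten_score <- function(hits, correct_rejections) {
  if (hits < 0 || hits > 10 || correct_rejections < 0 ||
      correct_rejections > 10)
    stop("counts must lie within 0-10")
  (hits + correct_rejections) >= 15
}

#' Run the quick TEN(HL) cascade
#'
#' Tests the frequency where HL_total first reaches 65 dB HL with the
#' probe 10 dB above its threshold in TEN at 65 dB HL/ERB_N; on a pass,
#' escalates to the 70- then 75-dB-HL frequencies with TEN at 70 and 75.
#' Each block presents 10 signal and 10 TEN-only trials in seeded random
#' order. The first failing tier fixes the probe for the adaptive test.
#'
#' @param a An `"audiogram"`; must reach 65 dB HL somewhere.
#' @param responder Function `(f_sig, l_sig, ten_level, is_catch)`
#'   returning logical; see [make_ten_responder()].
#' @param n_each Signal and TEN-only trials per block.
#' @return A list with `outcome` (`"dr_detected"`, `"no_dr_detected"`, or
#'   `"not_testable"`), `tier` (65/70/75 or `NA`), `f_sig`, `l_sig`, and a
#'   `scores` data frame (one row per tier tested).
#' @export
quick_ten_protocol <- function(a, responder, n_each = 10) {
  stopifnot(inherits(a, "audiogram"))
  scores <- data.frame(tier = integer(0), f_sig = numeric(0),
                       l_sig = numeric(0), hits = integer(0),
                       correct_rejections = integer(0), total = integer(0),
                       pass = logical(0))
  for (tier in c(65, 70, 75)) {
    f_t <- find_freq_at_hl(a, tier)
    if (is.na(f_t)) {
      if (tier == 65)
        return(list(outcome = "not_testable", tier = NA_integer_,
                    f_sig = NA_real_, l_sig = NA_real_, scores = scores))
      break  # loss never reaches this tier; remaining tiers untestable
    }
    l_s <- interpolate_hl(a, f_t) + 10  # 10 dB SL
    present <- sample(rep(c(TRUE, FALSE), each = n_each))
    yes <- vapply(seq_along(present),
                  function(i) responder(f_t, l_s, tier, !present[i]),
                  logical(1))
    hits <- sum(yes & present)
    cr <- sum(!yes & !present)
    pass <- ten_score(min(hits, 10), min(cr, 10))
    scores <- rbind(scores,
                    data.frame(tier = tier, f_sig = f_t, l_sig = l_s,
                               hits = hits, correct_rejections = cr,
                               total = hits + cr, pass = pass))
    if (!pass)
      return(list(outcome = "dr_detected", tier = tier, f_sig = f_t,
                  l_sig = l_s, scores = scores))
  }
  list(outcome = "no_dr_detected", tier = NA_integer_, f_sig = NA_real_,
       l_sig = NA_real_, scores = scores)
}
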