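test_that("the initial grid is two ascending 8-level blocks at -2 and -4 Cams", {
  sig <- signal_spec(1000, 75)
  g <- initial_grid(sig)
  expect_equal(nrow(g), 16)
  cam_sig <- cam_from_hz(1000)
  expect_equal(g$f_mask_hz[1], hz_from_cam(cam_sig - 2), tolerance = 1e-9)
  expect_equal(g$l_mask[1], 55)  # l_sig - 20
  expect_equal(g$f_mask_hz[9], hz_from_cam(cam_sig - 4), tolerance = 1e-9)
  expect_equal(g$l_mask[1:8], 75 + c(-20, -9, -6, -3, 0, 3, 6, 9))
  expect_equal(g$l_mask[9:16], g$l_mask[1:8])
  expect_true(all(diff(g$l_mask[1:8]) > 0))
  # levels outside bounds are clipped with a warning
  expect_warning(g2 <- initial_grid(signal_spec(1000, 88)), "clipped")
  expect_true(all(g2$l_mask <= 90))
})

test_that("mutual information matches its defining decomposition and bounds", {
  p <- fx_profile(4)
  sig <- fx_sig(p)
  prior <- build_prior(p$audiogram, sig)
  g <- prior$grid
  # point-mass posterior carries no information about any stimulus
  pm <- prior
  pm$prob[] <- 0
  pm$prob[g$cells_idx[5]] <- 1
  x <- list(f_mask = hz_from_cam(cam_from_hz(sig$f_sig) - 2), l_mask = 70)
  expect_equal(mutual_information(pm, x, sig, p$audiogram), 0)
  # two equiprobable cells with hit probabilities pinned at the rails
  # 0.01 / 0.99: a mild flat loss where the probe has a large sensation
  # level, one cell directly under a 60-dB masker, one well away from it
  af <- audiogram(c(100, 16000), c(30, 30))
  sigf <- signal_spec(1000, 75)
  pf <- build_prior(af, sigf)
  gf <- pf$grid
  cs <- cam_from_hz(1000)
  iA <- which.min(abs(gf$fe_cam - (cs - 2.5)))
  iB <- which.min(abs(gf$fe_cam - (cs - 0.5)))
  cA <- which(gf$cells_fe == iA & gf$cells_ohcl == 1)
  cB <- which(gf$cells_fe == iB & gf$cells_ohcl == 1)
  expect_length(cA, 1)
  expect_length(cB, 1)
  x2 <- list(f_mask = gf$fe_hz[iA], l_mask = 60)
  p_lo <- hit_probability(x2, list(fe_hz = gf$fe_hz[iA], ohcl = 0), sigf, af)
  p_hi <- hit_probability(x2, list(fe_hz = gf$fe_hz[iB], ohcl = 0), sigf, af)
  expect_equal(p_lo, 0.01, tolerance = 1e-9)
  expect_equal(p_hi, 0.99, tolerance = 1e-9)
  two <- pf
  two$prob[] <- 0
  two$prob[gf$cells_idx[c(cA, cB)]] <- 0.5
  expect_equal(mutual_information(two, x2, sigf, af),
               1 - binary_entropy(0.01), tolerance = 1e-9)
  # engine fast path agrees with the scalar definition
  eng <- fx_engine(4)
  pc <- prior$prob[g$cells_idx]
  mi_all <- deadregion:::.engine_mi(eng, pc)
  pick <- round(seq(1, nrow(eng$cand), length.out = 12))
  for (k in pick) {
    expect_equal(mi_all[k],
                 mutual_information(prior,
                                    list(f_mask = eng$cand$f_mask_hz[k],
                                         l_mask = eng$cand$l_mask[k]),
                                    sig, p$audiogram),
                 tolerance = 1e-9)
  }
  expect_true(all(mi_all >= 0 & mi_all <= 1))
})

test_that("stimulus selection respects weights, exclusion and determinism", {
  p <- fx_profile(4)
  sig <- fx_sig(p)
  eng <- fx_engine(4)
  cand <- eng$cand
  prior <- eng$prior
  pc <- prior$prob[prior$grid$cells_idx]
  mi <- deadregion:::.engine_mi(eng, pc)
  fe_hat <- map_fe(prior)
  prev <- hz_from_cam(fe_hat)  # exclude the region around the last masker
  # single positive-weight candidate is drawn with probability 1
  mi1 <- numeric(length(mi))
  far <- which(abs(cand$f_mask_cam - cam_from_hz(prev)) >= 2)
  mi1[far[1]] <- 0.5
  for (i in 1:5) {
    sel <- select_next_stimulus(prior, cand, fe_hat, prev, mi = mi1)
    expect_equal(sel$index, far[1])
  }
  # seeded draws reproduce exactly
  set.seed(99)
  s1 <- select_next_stimulus(prior, cand, fe_hat, prev, mi = mi)
  set.seed(99)
  s2 <- select_next_stimulus(prior, cand, fe_hat, prev, mi = mi)
  expect_identical(s1, s2)
  # empirical frequencies over many draws match the exact weights,
  # and excluded candidates never appear
  w <- mi * stats::dnorm(cand$f_mask_cam, fe_hat, 1.5)
  excl <- abs(cand$f_mask_cam - cam_from_hz(prev)) < 2
  w[excl] <- 0
  w <- w / sum(w)
  set.seed(1234)
  n_draw <- 2e4
  draws <- vapply(seq_len(n_draw), function(i)
    select_next_stimulus(prior, cand, fe_hat, prev, mi = mi)$index,
    numeric(1))
  expect_equal(sum(tabulate(draws, length(w))[excl]), 0)
  counts <- tabulate(draws, length(w))
  big <- which(w * n_draw >= 5)
  obs <- c(counts[big], n_draw - sum(counts[big]))
  expc <- c(w[big], 1 - sum(w[big]))
  keep <- expc > 0
  chi <- suppressWarnings(stats::chisq.test(obs[keep], p = expc[keep]))
  expect_gt(chi$p.value, 0.01)
})

test_that("the stopping rule needs three consecutive quiet trials", {
  expect_true(stopping_check(c(0.05, 0.04, 0.03), 0.1))
  expect_false(stopping_check(c(0.05, 0.2, 0.03), 0.1))
  expect_false(stopping_check(c(0.04, 0.03), 0.1))
  expect_true(stopping_check(c(NA, NA, 0.5, 0.09, 0.02, 0.01), 0.1))
})

test_that("a full session presents 124 trials and is seed-deterministic", {
  ses <- fx_session(4, 11)
  expect_equal(nrow(ses$trials), 124)  # 4 practice + 100 inference + 20 catch
  expect_equal(sum(ses$trials$phase == "practice"), 4)
  expect_equal(sum(ses$trials$is_catch), 20)
  expect_equal(sum(!ses$trials$is_catch & ses$trials$phase != "practice"), 100)
  expect_equal(length(ses$fe_map_trace), 100)
  expect_equal(length(ses$mi_trace), 100)
  expect_true(all(is.na(ses$mi_trace[1:16])))
  expect_true(all(!is.na(ses$mi_trace[17:100])))
  p <- fx_profile(4)
  sig <- fx_sig(p)
  again <- run_session(session_config(rng_seed = 11),
                       make_responder(p, sig), p$audiogram, sig,
                       engine = fx_engine(4))
  expect_identical(again$trials, ses$trials)
  expect_identical(again$final_fe_cam, ses$final_fe_cam)
})

test_that("selected maskers cluster near the true edge frequency", {
  p <- fx_profile(4)
  ses <- fx_session(4, 11)
  act <- ses$trials$phase == "active" & !ses$trials$is_catch
  dist <- abs(cam_from_hz(ses$trials$f_mask_hz[act]) -
                cam_from_hz(p$true_fe_hz))
  expect_lt(stats::median(dist), 3)
})

test_that("queried information declines over the run", {
  for (i in c(3, 4, 6)) {
    ses <- fx_session(i, 11)
    mi <- ses$mi_trace[!is.na(ses$mi_trace)]
    expect_lt(mean(mi[41:50]), mean(mi[1:10]))
  }
})

test_that("the Gaussian weighting is an efficiency device, not a crutch", {
  # with the weighting effectively removed, recovery still succeeds
  p <- fx_profile(4)
  sig <- fx_sig(p)
  truth <- cam_from_hz(p$true_fe_hz)
  for (s in 1:3) {
    ses <- run_session(session_config(rng_seed = s, weight_sigma = 1e6),
                       make_responder(p, sig), p$audiogram, sig,
                       engine = fx_engine(4))
    expect_lt(abs(ses$fe_map_trace[100] - truth), 0.5)
  }
})

test_that("early stopping triggers on a persistently quiet information trace", {
  p <- fx_profile(3)
  sig <- fx_sig(p)
  cfg <- session_config(rng_seed = 2, early_stop = TRUE,
                        stop_mi_threshold = 0.1)
  ses <- run_session(cfg, make_responder(p, sig), p$audiogram, sig,
                     engine = fx_engine(3))
  expect_true(ses$stopped)
  expect_lt(length(ses$fe_map_trace), 100)
  mi <- ses$mi_trace[!is.na(ses$mi_trace)]
  expect_true(all(utils::tail(mi, 3) < 0.1))
})
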