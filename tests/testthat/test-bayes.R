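test_that("the prior is uniform over admissible cells with the stated constraints", {
  p <- fx_profile(4)
  sig <- fx_sig(p)
  prior <- build_prior(p$audiogram, sig)
  g <- prior$grid
  # uniform over the support, zero outside, unit mass
  vals <- prior$prob[g$mask]
  expect_equal(sum(prior$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(vals - 1 / sum(g$mask)) < 1e-15))
  expect_true(all(prior$prob[!g$mask] == 0))
  # f_e bins spaced 0.1 Cam and strictly below the probe
  expect_equal(unique(round(diff(g$fe_cam), 10)), 0.1)
  expect_lt(max(g$fe_cam), cam_from_hz(sig$f_sig))
  # OHCL above HL_total(f_e) inadmissible
  over <- outer(g$hl_fe, g$ohcl_db, function(h, o) o > h + 1e-9)
  expect_true(all(prior$prob[over] == 0))
  # quiet-audibility constraint empties rows where the probe is inaudible
  inaud <- g$e_sig < g$hl_fe - 1e-9
  expect_true(all(rowSums(prior$prob)[inaud] == 0))
  # the marginal support ends at the probe frequency
  m <- marginal_fe(prior)
  expect_lt(max(m$fe_cam[m$prob > 0]), cam_from_hz(sig$f_sig))
})

test_that("prior construction fails informatively on impossible setups", {
  # probe far too quiet to be audible anywhere: empty support
  a <- audiogram(c(100, 16000), c(90, 95))
  expect_error(build_prior(a, signal_spec(12000, 20)), "support is empty")
  # audiogram not covering the candidate range
  b <- audiogram(c(800, 2000), c(40, 90))
  expect_error(build_prior(b, signal_spec(1500, 80)), "cover")
})

test_that("sequential updates equal the brute-force batch product", {
  p <- fx_profile(2)
  sig <- fx_sig(p)
  prior <- build_prior(p$audiogram, sig)
  g <- prior$grid
  # restrict to a 6-cell toy support
  idx6 <- g$cells_idx[round(seq(1, length(g$cells_idx), length.out = 6))]
  toy <- prior
  toy$prob[] <- 0
  toy$prob[idx6] <- 1 / 6
  cam_sig <- cam_from_hz(sig$f_sig)
  trials <- list(
    list(x = list(f_mask = hz_from_cam(cam_sig - 2), l_mask = 60), y = TRUE),
    list(x = list(f_mask = hz_from_cam(cam_sig - 4), l_mask = 74), y = FALSE),
    list(x = list(f_mask = hz_from_cam(cam_sig - 1), l_mask = 80), y = FALSE),
    list(x = list(f_mask = hz_from_cam(cam_sig - 3), l_mask = 50), y = TRUE),
    list(x = list(f_mask = hz_from_cam(cam_sig - 2.5), l_mask = 66), y = TRUE))
  seqp <- toy
  for (t in trials) seqp <- update_posterior(seqp, t, sig, p$audiogram)
  # independent oracle: per-cell product of scalar likelihoods
  fe_i <- row(g$mask)[idx6]
  oh_j <- col(g$mask)[idx6]
  w <- vapply(seq_along(idx6), function(k) {
    prod(vapply(trials, function(t) {
      ph <- hit_probability(t$x, list(fe_hz = g$fe_hz[fe_i[k]],
                                      ohcl = g$ohcl_db[oh_j[k]]),
                            sig, p$audiogram)
      if (t$y) ph else 1 - ph
    }, numeric(1)))
  }, numeric(1))
  expect_equal(seqp$prob[idx6], w / sum(w), tolerance = 1e-12)
  expect_true(all(seqp$prob[-idx6] == 0))
})

test_that("catch trials leave the posterior unchanged and practice errors", {
  p <- fx_profile(4)
  sig <- fx_sig(p)
  prior <- build_prior(p$audiogram, sig)
  t_catch <- list(x = list(f_mask = 700, l_mask = 60), y = TRUE,
                  is_catch = TRUE)
  expect_identical(update_posterior(prior, t_catch, sig, p$audiogram)$prob,
                   prior$prob)
  expect_error(update_posterior(prior, list(x = NULL, y = TRUE,
                                            is_practice = TRUE),
                                sig, p$audiogram), "practice")
})

test_that("posterior mass is conserved and order does not matter", {
  p <- fx_profile(4)
  sig <- fx_sig(p)
  prior <- build_prior(p$audiogram, sig)
  set.seed(101)
  cam_sig <- cam_from_hz(sig$f_sig)
  trials <- lapply(1:20, function(i)
    list(x = list(f_mask = hz_from_cam(cam_sig - runif(1, 0.2, 6)),
                  l_mask = runif(1, 30, 88)),
         y = runif(1) < 0.5))
  post <- prior
  for (t in trials) {
    post <- update_posterior(post, t, sig, p$audiogram)
    expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  }
  post_perm <- prior
  for (t in trials[sample(20)]) {
    post_perm <- update_posterior(post_perm, t, sig, p$audiogram)
  }
  expect_equal(post_perm$prob, post$prob, tolerance = 1e-10)
})

test_that("marginals and the MAP follow the joint posterior", {
  # hand-built 2 x 2 joint (rows = f_e): row sums (0.3, 0.7)
  fake <- structure(list(
    grid = list(fe_cam = c(12.0, 12.1), fe_hz = hz_from_cam(c(12.0, 12.1)),
                ohcl_db = c(0, 2.5),
                mask = matrix(TRUE, 2, 2),
                cells_idx = 1:4, cells_fe = c(1L, 2L, 1L, 2L),
                cells_ohcl = c(1L, 1L, 2L, 2L)),
    prob = matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)), class = "drt_posterior")
  m <- marginal_fe(fake)
  expect_equal(m$prob, c(0.3, 0.7))
  expect_equal(sum(m$prob), 1)
  expect_equal(map_fe(fake), 12.1)
  # point mass
  fake$prob <- matrix(c(0, 0, 1, 0), 2, 2)
  expect_equal(marginal_fe(fake)$prob, c(1, 0))
  expect_equal(map_fe(fake), 12.0)
  # exact tie breaks toward the lower bin
  fake$prob <- matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2)
  expect_equal(map_fe(fake), 12.0)
  # uniform joint over a masked 3 x 4 grid: marginal weighted by row counts
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE,
                   TRUE, FALSE, FALSE, TRUE,
                   TRUE, TRUE, TRUE, TRUE), 3, 4)
  pm <- matrix(0, 3, 4)
  pm[mask] <- 1 / sum(mask)
  fake2 <- structure(list(
    grid = list(fe_cam = c(10, 10.1, 10.2), fe_hz = hz_from_cam(c(10, 10.1, 10.2)),
                ohcl_db = seq(0, 7.5, 2.5), mask = mask),
    prob = pm), class = "drt_posterior")
  expect_equal(marginal_fe(fake2)$prob, rowSums(mask) / sum(mask))
})

test_that("the posterior concentrates for a near-noiseless responder", {
  p <- fx_profile(3)
  sharp <- listener_profile(p$true_fe_hz, p$true_ohcl, p$audiogram,
                            psych_sd = 0.5, false_alarm_rate = 0,
                            label = "sharp")
  sig <- fx_sig(p)
  eng <- fx_engine(3)
  ses <- run_session(session_config(rng_seed = 5, sd = 0.5),
                     make_responder(sharp, sig), p$audiogram, sig,
                     engine = eng)
  # 95% credible-interval width of the f_e marginal per inference trial
  ci_width <- function(w) {
    g <- ses$grid
    m <- rowsum(w, g$cells_fe)
    cams <- g$fe_cam[as.integer(rownames(m))]
    cs <- cumsum(m[order(cams)])
    cams <- sort(cams)
    diff(cams[c(which(cs >= 0.025)[1], which(cs >= 0.975)[1])])
  }
  lp <- log(ses$prior_prob)
  widths <- vapply(seq_len(ncol(ses$loglik)), function(n) {
    w <- exp(lp + rowSums(ses$loglik[, 1:n, drop = FALSE]))
    ci_width(w / sum(w))
  }, numeric(1))
  expect_lt(mean(widths[51:100]), mean(widths[1:20]))
  expect_lte(widths[100], widths[30])
})

test_that("posterior CSV exports carry the full distribution", {
  ses <- fx_session(4, 11)
  path <- tempfile(fileext = ".csv")
  write_posterior_csv(ses$posterior, path)
  d <- read.csv(path)
  expect_equal(sum(d$probability), 1, tolerance = 1e-9)
  expect_equal(nrow(d),
               length(ses$grid$fe_cam) * length(ses$grid$ohcl_db))
  write_marginal_csv(ses$posterior, path)
  m <- read.csv(path)
  expect_equal(m$probability, marginal_fe(ses$posterior)$prob,
               tolerance = 1e-12)
})
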