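test_that("ensemble rotation is the circular mean of per-unit shifts", {
  expect_equal(ensemble_rotation(rep(90, 5))$mean_deg, 90)
  er <- ensemble_rotation(c(80, 100))
  expect_equal(er$mean_deg, 90)
  expect_equal(er$n, 2L)
  expect_error(ensemble_rotation(45), "at least 2")
  expect_equal(ensemble_rotation(c(NA, 170, -170))$mean_deg, 180)
})

test_that("pairwise PFD rigidity detects coherent vs scrambled rotations", {
  set.seed(15)
  pre <- runif(12, 0, 360)
  expect_equal(pair_rigidity(pre, (pre + 90) %% 360), 1, tolerance = 1e-9)
  ## scrambled post-PFDs: correlation collapses
  expect_lt(abs(pair_rigidity(pre, runif(12, 0, 360))), 0.45)
  ## monotone degradation with per-unit jitter
  r10 <- pair_rigidity(pre, (pre + 90 + rnorm(12, 0, 10)) %% 360)
  r40 <- pair_rigidity(pre, (pre + 90 + rnorm(12, 0, 40)) %% 360)
  expect_gt(r10, r40)
  expect_gt(r10, 0.5)
  expect_error(pair_rigidity(pre[1:2], pre[1:2]), "at least 3")
})

test_that("the realignment inclusion rule admits only shifted trials", {
  expect_identical(trial_inclusion(c(90, -45, 10, -17.2, 17.19)),
                   c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("per-unit PFD shifts recover an imposed rotation", {
  ev <- data.frame(time_s = 300, event = "rotate", value = 90)
  s <- quick_session(seed = 51, duration = 660, nA = 10, nB = 0, events = ev,
                     reference = c(rigid_ref, list(relax_tau = 5, gain = 1)))
  sh <- pfd_shifts(s, s$units$unit_id, c(0, 300), c(360, 660))
  expect_true(all(abs(wrap_diff(sh[!is.na(sh)], 90)) < 10))
  er <- ensemble_rotation(sh)
  expect_lt(abs(wrap_diff(er$mean_deg, 90)), 5)
})

test_that("index-reassignment nulls flag real rotations and pass quiet trials", {
  ev <- data.frame(time_s = 300, event = "rotate", value = 90)
  s <- quick_session(seed = 52, duration = 540, nA = 8, nB = 0, events = ev,
                     reference = c(rigid_ref, list(relax_tau = 5, gain = 1)))
  set.seed(3)
  rs <- rotation_significance(s, s$units$unit_id, c(180, 300), c(360, 480),
                              n = 200)
  expect_true(rs$significant)
  expect_gte(rs$frac_exceeding, 0.5)
  ## rule is boundary-inclusive by construction
  expect_identical(rs$significant, rs$frac_exceeding >= 0.5)
  s0 <- quick_session(seed = 53, duration = 540, nA = 8, nB = 0,
                      reference = rigid_ref)
  set.seed(4)
  rs0 <- rotation_significance(s0, s0$units$unit_id, c(180, 300), c(360, 480),
                               n = 200)
  expect_false(rs0$significant)
})

test_that("running median smoothing matches a brute-force oracle", {
  const <- rep(42, 300)
  expect_equal(smooth_error(const), const)
  ## single outlier removed
  spiky <- c(rep(10, 150), 170, rep(10, 149))
  expect_true(all(smooth_error(spiky) == 10))
  set.seed(16)
  x <- cumsum(rnorm(500, 0, 3))
  got <- smooth_error(x, window_s = 5, dt = 0.02)
  h <- 125
  oracle <- vapply(seq_along(x), function(i)
    median(x[max(1, i - h):min(length(x), i + h)]), numeric(1))
  expect_equal(got, wrap_deg(oracle))
})

test_that("error cross-correlation finds imposed lags and matches a direct oracle", {
  set.seed(17)
  e <- cumsum(rnorm(3750, 0, 2))
  lr <- error_crosscorr(e, e, n_null = 0)
  expect_equal(lr$peak_lag_s, 0)
  expect_equal(lr$peak_corr, 1, tolerance = 1e-9)
  ## B delayed by 200 ms: A leads, positive lag
  eB <- c(rep(e[1], 10), e[1:3740])
  expect_equal(error_crosscorr(e, eB, n_null = 0)$peak_lag_s, 0.2)
  ## full curve equals a per-lag Pearson oracle
  set.seed(18)
  x <- rnorm(400); y <- rnorm(400)
  lr2 <- error_crosscorr(x, y, max_lag_s = 1, n_null = 0)
  L <- 50
  oracle <- vapply(-L:L, function(l) {
    if (l >= 0) cor(x[1:(400 - l)], y[(1 + l):400])
    else cor(x[(1 - l):400], y[1:(400 + l)])
  }, numeric(1))
  ux <- x; uy <- y  # already unwrapped scale-free inputs
  expect_equal(lr2$corr, oracle, tolerance = 1e-9)
  ## independent traces: null peak lags spread over the grid
  set.seed(19)
  lr3 <- error_crosscorr(cumsum(rnorm(2000)), cumsum(rnorm(2000)), n_null = 50)
  expect_length(lr3$null_peak_lag_s, 50)
  expect_gt(diff(range(lr3$null_peak_lag_s)), 1)
})

test_that("difference profiles trough at the imposed offset and match brute force", {
  set.seed(20)
  x <- cumsum(rnorm(2750, 0, 2)) %% 360
  dp <- difference_profile(x, x)
  expect_equal(dp$trough_lag_s, 0)
  expect_equal(min(dp$profile_deg), 0)
  ## 200 ms imposed delay of B
  xB <- c(rep(x[1], 10), x[1:2740])
  expect_equal(difference_profile(x, xB)$trough_lag_s, 0.2)
  ## brute-force recomputation at a few lags
  L <- 250; spb <- 250
  ai <- (L + 1):(L + 7 * spb)
  for (l in c(-100, 0, 37)) {
    med <- vapply(split(wrap_diff(x[ai], x[ai + l]), rep(1:7, each = spb)),
                  median, numeric(1))
    expect_equal(dp$profile_deg[L + 1 + l], median(abs(med)))
  }
  expect_error(difference_profile(x[1:1000], x[1:1000]), "35 s")
})

test_that("drift analysis separates shared from independent reference drift", {
  ev <- data.frame(time_s = 540, event = "cue_off", value = 0)
  mk <- function(seed, indep) {
    cfg <- sim_config(duration = 1560, n_units = c(A = 12, B = 12), events = ev,
                      reference = list(independent = indep),
                      tuning = list(frac_untuned = c(A = 0, B = 0),
                                    kappa_range = c(4, 4), peak_range = c(40, 40)))
    s <- simulate_session(cfg, seed = seed)
    tA <- predict(hd_decoder(s, "A", c(0, 300)))
    tB <- predict(hd_decoder(s, "B", c(0, 300)))
    drift_analysis(tA, tB, s$events, s$tracking, window = c(300, 1560),
                   n_null = 50)
  }
  set.seed(5)
  dr <- mk(54, FALSE)
  expect_gt(dr$corr["overall"], quantile(dr$null$overall, 0.99))
  expect_true(all(c(TRUE, FALSE) %in% dr$bins$cue_on))
  ## column-normalized 2-D histogram
  expect_lte(max(dr$hist2d), 1)
  expect_true(all(apply(dr$hist2d, 2, max) %in% c(0, 1)))
  set.seed(6)
  dr0 <- mk(55, TRUE)
  expect_lt(dr0$corr["overall"], quantile(dr0$null$overall, 0.99))
})

test_that("zero-diffusion darkness produces no drift", {
  ev <- data.frame(time_s = 420, event = "cue_off", value = 0)
  s <- quick_session(seed = 56, duration = 900, nA = 12, nB = 12, events = ev,
                     reference = rigid_ref)
  tA <- predict(hd_decoder(s, "A", c(0, 300)))
  tB <- predict(hd_decoder(s, "B", c(0, 300)))
  dr <- drift_analysis(tA, tB, s$events, s$tracking, window = c(300, 900),
                       n_null = 0)
  expect_lt(median(abs(dr$bins$driftA_deg)), 5)
  expect_lt(median(abs(dr$bins$driftB_deg)), 5)
})
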