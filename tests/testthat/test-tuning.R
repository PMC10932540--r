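test_that("tuning curves conserve spike counts exactly", {
  s <- quick_session(seed = 31, duration = 120, nA = 4, nB = 0)
  for (id in s$units$unit_id) {
    tc <- compute_tuning_curve(s$spikes[[id]], s$tracking)
    expect_identical(sum(tc$counts), tc$n_spikes)
    expect_equal(sum(tc$rate * tc$occupancy, na.rm = TRUE), tc$n_spikes,
                 tolerance = 1e-12)
  }
  expect_error(compute_tuning_curve(1:3, s$tracking, rbind(c(500, 600))),
               "empty mask")
})

test_that("tuning curves bin spikes by the heading of the nearest sample", {
  trk <- data.frame(time_s = seq(0, 99.98, by = 0.02),
                    hd_deg = rep(c(45, 200), length.out = 5000))
  ## spikes only at samples where heading is in [40, 50)
  spk <- trk$time_s[trk$hd_deg == 45][1:100] + 0.001
  tc <- compute_tuning_curve(spk, trk)
  expect_equal(tc$counts[5], 100)
  expect_equal(sum(tc$counts[-5]), 0)
  ## zero spikes: zero rates, occupancy preserved
  tc0 <- compute_tuning_curve(numeric(0), trk)
  expect_equal(tc0$n_spikes, 0)
  expect_true(all(tc0$rate[tc0$occupancy > 0] == 0))
  expect_equal(sum(tc0$occupancy), 100)
})

test_that("directional information matches closed forms and a brute-force oracle", {
  tc1 <- make_tc(c(36, rep(0, 35)))
  expect_equal(directional_information(tc1), log2(36), tolerance = 1e-12)
  expect_equal(directional_information(make_tc(rep(7, 36))), 0, tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    r <- rexp(36, 1 / 5); occ <- runif(36, 0.5, 2)
    tc <- make_tc(r, occ)
    p <- occ / sum(occ); lbar <- sum(p * r)
    oracle <- 0
    for (b in 1:36) if (r[b] > 0)
      oracle <- oracle + (r[b] / lbar) * log2(r[b] / lbar) * p[b]
    expect_equal(directional_information(tc), oracle, tolerance = 1e-12)
    expect_gte(directional_information(tc), 0)
  }
  expect_error(directional_information(make_tc(rep(0, 36))), "zero mean rate")
})

test_that("smoothing preserves mass and satisfies the Gaussian semigroup", {
  flat <- make_tc(rep(4, 36))
  expect_equal(smooth_tuning_curve(flat)$rate, flat$rate, tolerance = 1e-9)
  delta <- make_tc(c(rep(0, 9), 36, rep(0, 26)))
  sm <- smooth_tuning_curve(delta)
  expect_equal(sum(sm$rate * sm$occupancy), 36, tolerance = 1e-9)
  expect_equal(sm$rate[9], sm$rate[11], tolerance = 1e-9)  # symmetric spread
  set.seed(13)
  tc <- make_tc(rexp(36, 1 / 3), runif(36, 0.5, 2))
  twice <- smooth_tuning_curve(smooth_tuning_curve(tc, 1), 1)
  once <- smooth_tuning_curve(tc, sqrt(2))
  expect_equal(twice$rate, once$rate, tolerance = 1e-9)
})

test_that("resultant and PFD come from the rate-weighted circular mean", {
  one <- make_tc(c(rep(0, 12), 20, rep(0, 23)))
  rp <- resultant_and_pfd(one)
  expect_equal(rp$pfd_deg, 125)
  expect_equal(rp$R, 1)
  expect_lt(resultant_and_pfd(make_tc(rep(3, 36)))$R, 1e-12)
  expect_error(resultant_and_pfd(make_tc(rep(0, 36))), "all-zero")
  ## recovery from a generated von Mises curve
  rp2 <- resultant_and_pfd(make_tc(vm_rate(233, 4, 30, 1)))
  expect_lt(abs(wrap_diff(rp2$pfd_deg, 233)), 5)
})

test_that("circular peak finding applies prominence, width and distance rules", {
  expect_equal(nrow(find_peaks_circular(make_tc(rep(5, 36)))), 0)
  two_far <- make_tc(vm_rate(40, 4, 30) + vm_rate(220, 4, 25))
  expect_equal(nrow(find_peaks_circular(two_far)), 2)
  two_near <- make_tc(vm_rate(40, 4, 30) + vm_rate(100, 4, 25))
  expect_equal(nrow(find_peaks_circular(two_near)), 1)  # 60 deg < min distance
  ## wrap-around peak is found once
  wrapped <- make_tc(vm_rate(0, 4, 30))
  pk <- find_peaks_circular(wrapped)
  expect_equal(nrow(pk), 1)
  ## low prominence rejected
  faint <- make_tc(vm_rate(90, 4, 10))
  expect_equal(nrow(find_peaks_circular(faint, min_prominence = 11)), 0)
  expect_equal(nrow(find_peaks_circular(faint, min_prominence = 5)), 1)
})

test_that("von Mises fits recover exact curves and flag degenerate ones", {
  tc <- make_tc(2 + 30 * exp(4 * (cos(pi / 180 * (th_centers - 130)) - 1)) /
                  (2 * pi * besselI(4, 0, expon.scaled = TRUE)))
  f <- fit_von_mises(tc, n_peaks = 1)
  expect_true(f$converged)
  expect_equal(f$coefficients$c1, 2, tolerance = 1e-6)
  expect_equal(f$coefficients$peaks$scale, 30, tolerance = 1e-5)
  expect_equal(f$coefficients$peaks$location_deg, 130, tolerance = 1e-5)
  expect_equal(f$coefficients$peaks$kappa, 4, tolerance = 1e-5)
  expect_equal(f$kappa_largest, 4, tolerance = 1e-5)
  ## two-peak curve: largest-peak concentration reported
  tc2 <- make_tc(vm_rate(40, 6, 30) + vm_rate(220, 2, 12))
  f2 <- fit_von_mises(tc2, n_peaks = 2)
  expect_true(f2$converged)
  expect_equal(f2$kappa_largest, 6, tolerance = 0.2)
  ## flat curve: either flagged or fitted as (near-)flat
  ff <- fit_von_mises(make_tc(rep(5, 36)), n_peaks = 1)
  if (ff$converged) expect_lt(max(abs(ff$fitted - 5)), 0.2)
})

test_that("von Mises fits recover parameters from Poisson-noisy sessions", {
  s <- quick_session(seed = 33, duration = 600, nA = 10, nB = 0,
                     reference = rigid_ref, kappa = c(4, 4), peak = c(30, 50))
  hits <- vapply(s$units$unit_id, function(id) {
    tc <- compute_tuning_curve(s$spikes[[id]], s$tracking)
    f <- fit_von_mises(tc, n_peaks = 1)
    truth <- s$truth$units[id, ]
    f$converged &&
      abs(wrap_diff(f$coefficients$peaks$location_deg, truth$pfd)) <= 10 &&
      abs(f$coefficients$peaks$kappa - truth$kappa) / truth$kappa <= 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("shuffle thresholds and the two-segment rule classify units correctly", {
  s <- quick_session(seed = 34, duration = 600, nA = 2, nB = 0)
  seg1 <- rbind(c(0, 300)); seg2 <- rbind(c(300, 600))
  set.seed(1)
  nul <- shuffle_null(s$spikes[["A1"]], s$tracking, seg1, n = 100)
  expect_true(all(nul$thresholds >= 0))
  expect_identical(dim(nul$distributions), c(100L, 3L))
  expect_error(shuffle_null(s$spikes[["A1"]], s$tracking, rbind(c(0, 30))),
               "60 s")
  ## tuned unit passes on both segments
  set.seed(2)
  cl <- classify_hd_unit(s$spikes[["A1"]], s$tracking, seg1, seg2,
                         n_shuffle = 200)
  expect_identical(cl$label, "HD")
  ## tuned on segment 1 only: not HD
  untuned_half <- sort(runif(1500, 300, 600))
  hybrid <- sort(c(s$spikes[["A1"]][s$spikes[["A1"]] < 300], untuned_half))
  set.seed(3)
  cl2 <- classify_hd_unit(hybrid, s$tracking, seg1, seg2, n_shuffle = 200)
  expect_identical(cl2$label, "non-HD")
  expect_false(cl2$is_hd)
  ## zero-spike unit is unclassifiable, not non-HD
  cl3 <- classify_hd_unit(numeric(0), s$tracking, seg1, seg2)
  expect_identical(cl3$label, "unclassifiable")
})

test_that("angular velocity derives from decimated unwrapped heading", {
  trk_const <- data.frame(time_s = seq(0, 99.98, 0.02), hd_deg = rep(123, 5000))
  expect_true(all(abs(angular_velocity(trk_const)) < 1e-9))
  trk_rot <- data.frame(time_s = seq(0, 99.98, 0.02),
                        hd_deg = (30 * seq(0, 99.98, 0.02)) %% 360)
  av <- angular_velocity(trk_rot)
  inner <- av[100:4900]
  expect_lt(max(abs(inner - 30)), 1e-6)
  ## matches an independent recomputation on synthetic heading
  s <- quick_session(seed = 35, duration = 100, nA = 1, nB = 0)
  av2 <- angular_velocity(s$tracking)
  u <- s$tracking$hd_deg[1] +
    c(0, cumsum(wrap_diff(s$tracking$hd_deg[-1], s$tracking$hd_deg[-5000])))
  ds <- seq(1, 5000, by = 25)
  ref <- approx((s$tracking$time_s[ds[-1]] + s$tracking$time_s[ds[-length(ds)]]) / 2,
                diff(u[ds]) / 0.5, xout = s$tracking$time_s, rule = 2)$y
  expect_lt(max(abs(av2 - ref)), 1e-9)
})
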