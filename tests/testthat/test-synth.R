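test_that("sessions regenerate bit-identically under a fixed seed", {
  cfg <- sim_config(duration = 60, n_units = c(A = 3, B = 3),
                    connections = data.frame(pre = 1, post = 1,
                                             latency_ms = 2.5, prob = 0.3,
                                             jitter_ms = 0.2))
  s1 <- simulate_session(cfg, seed = 42)
  s2 <- simulate_session(cfg, seed = 42)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$tracking, s2$tracking)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(cfg, seed = 43)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("heading follows the integrated angular-velocity process", {
  cfg0 <- sim_config(duration = 20, heading = list(sigma_av = 0))
  set.seed(1)
  h0 <- simulate_heading(cfg0)
  expect_lt(diff(range(h0$heading_deg)), 1e-9)  # zero AV: constant heading
  ## heading re-derivable from AV integration
  cfg <- sim_config(duration = 120)
  set.seed(2)
  h <- simulate_heading(cfg)
  redo <- h$heading_deg[1] - h$av_deg_s[1] * 1e-3 + cumsum(h$av_deg_s) * 1e-3
  expect_lt(max(abs(redo - h$heading_deg)), 1e-9)
  ## OU stationary SD of AV within 10% at 4e5 steps
  cfg2 <- sim_config(duration = 400, heading = list(sigma_av = 45, tau_av = 0.5))
  set.seed(3)
  h2 <- simulate_heading(cfg2)
  expect_lt(abs(sd(h2$av_deg_s) - 45) / 45, 0.10)
  ## 50 Hz export aligns with the 1 kHz latent
  expect_equal(h$tracking$hd_deg, h$heading_deg[seq(1, 120000, by = 20)] %% 360)
})

test_that("spike generation follows the von Mises rate model", {
  cfg <- sim_config(duration = 300, n_units = c(A = 1, B = 0),
                    reference = rigid_ref)
  set.seed(8)
  hd <- simulate_heading(cfg)
  off <- matrix(0, length(hd$heading_deg), 2, dimnames = list(NULL, c("A", "B")))
  ## untuned unit: homogeneous Poisson at the base rate
  u0 <- data.frame(region = "A", pfd = 0, kappa = 0, peak = 0, base = 8,
                   row.names = "A1")
  n0 <- length(simulate_spikes(u0, hd$heading_deg, off)[["A1"]])
  expect_lt(abs(n0 - 8 * 300), 4 * sqrt(8 * 300))
  ## kappa = 50: at least 99% of spikes within 30 degrees of the PFD
  u1 <- data.frame(region = "A", pfd = 90, kappa = 50, peak = 40, base = 0,
                   row.names = "A1")
  st <- simulate_spikes(u1, hd$heading_deg, off)[["A1"]]
  hd_at <- hd$heading_deg[pmin(floor(st * 1000) + 1, length(hd$heading_deg))]
  expect_gte(mean(abs(wrap_diff(hd_at, 90)) <= 30), 0.99)
  ## expected total count matches the rate integral
  u2 <- data.frame(region = "A", pfd = 200, kappa = 3, peak = 25, base = 1,
                   row.names = "A1")
  lam <- 1 + 25 * exp(3 * (cos(pi / 180 * (hd$heading_deg - 200)) - 1))
  expected <- sum(lam) * 1e-3
  counts <- replicate(30, length(simulate_spikes(u2, hd$heading_deg, off)[["A1"]]))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 30))
})

test_that("transmission injection inserts the right spikes", {
  set.seed(9)
  pre <- sort(runif(1000, 0, 600))
  post <- sort(runif(500, 0, 600))
  expect_identical(as.numeric(inject_transmission(pre, post, 0, 2.5)), post)
  out <- inject_transmission(pre, post, 1, 3, jitter_ms = 0)
  expect_equal(attr(out, "n_inserted"), 1000)
  expect_length(out, 1500)
  expect_true(all(sort(c(post, pre + 0.003)) == out))
  ## binomial insertion count
  n_ins <- attr(inject_transmission(sort(runif(24000, 0, 1200)), post,
                                    0.05, 2.5, 0.2), "n_inserted")
  expect_lt(abs(n_ins - 1200), 3 * sqrt(1200))
  expect_error(inject_transmission(pre, post, 1.2, 2.5), "prob")
  expect_error(inject_transmission(pre, post, 0.5, 0.5), "latency")
})

test_that("waveform templates sit on the right side of the RS/FS cutoff", {
  rs <- waveform_features(synth_waveform(0.6), 30000)
  expect_equal(rs$peak_to_trough_ms, 0.6, tolerance = 0.011)
  expect_identical(rs$class, "RS")
  fs <- waveform_features(synth_waveform(0.25, ahp_sd_ms = 0.1), 30000)
  expect_lt(fs$peak_to_trough_ms, 0.42)
  expect_identical(fs$class, "FS")
  ## symmetric flanks give symmetry 0
  t <- seq(0, 3, by = 1 / 30)
  sym <- 0.3 * exp(-(t - 0.6)^2 / 0.02) - exp(-(t - 1)^2 / 0.02) +
    0.3 * exp(-(t - 1.4)^2 / 0.02)
  expect_lt(abs(waveform_features(sym, 30000)$symmetry), 1e-9)
})

test_that("rotation events move the reference by gain x magnitude", {
  ev <- data.frame(time_s = 60, event = "rotate", value = 90)
  cfg <- sim_config(duration = 240, events = ev,
                    reference = c(rigid_ref, list(relax_tau = 10, gain = 0.5)))
  set.seed(10)
  offs <- simulate_offsets(cfg)
  expect_lt(max(abs(offs$offset[1:59000, "A"])), 1e-9)
  ## after 10 relaxation time constants: at gain x magnitude
  expect_equal(unname(offs$offset[200000, "A"]), 45, tolerance = 1e-3)
  expect_equal(offs$offset[, "A"], offs$offset[, "B"])
})
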