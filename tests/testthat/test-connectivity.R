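test_that("cross-correlograms count spike pairs exactly", {
  set.seed(21)
  pre <- sort(runif(300, 0, 60))
  post <- pre + 0.00232  # every post spike 2.32 ms after a pre spike
  ccg <- compute_ccg(pre, post)
  i <- which(ccg$lag_s > 0.002 & ccg$lag_s < 0.0025)
  expect_gte(ccg$counts[i], 300)
  ## all mass at positive short lags beyond chance sits in that bin
  expect_error(compute_ccg(numeric(0), post), "empty")
  ## total equals a brute-force all-pairs count
  post2 <- sort(runif(400, 0, 60))
  ccg2 <- compute_ccg(pre, post2)
  d <- round(outer(post2, pre, "-") / 1e-5) * 1e-5
  expect_identical(sum(ccg2$counts), sum(d >= -0.05 & d <= 0.05))
  ## and the full histogram matches a direct hist oracle
  dd <- d[d >= -0.05 & d <= 0.05]
  idx <- pmin(floor((dd + 0.05) / 5e-4 + 1e-6) + 1, 200)
  expect_identical(ccg2$counts, tabulate(idx, 200))
  ## independent Poisson pairs: flat correlogram at the rate product
  p1 <- sort(runif(12000, 0, 1200)); p2 <- sort(runif(12000, 0, 1200))
  ccg3 <- compute_ccg(p1, p2)
  expect_lt(abs(mean(ccg3$counts) - 60), 5)
})

test_that("the convolved baseline is flat-preserving and mass-conserving", {
  flat <- compute_ccg(sort(runif(5000, 0, 600)), sort(runif(5000, 0, 600)))
  flat$counts <- rep(40L, 200)
  b <- ccg_baseline(flat)
  expect_lt(max(abs(b - 40)), 1e-9)
  delta <- flat; delta$counts <- c(rep(0L, 99), 1000L, rep(0L, 100))
  bd <- ccg_baseline(delta)
  expect_equal(sum(bd), 1000, tolerance = 1e-6)
  expect_equal(which.max(bd), 100)
  ## matches a direct reflected-padding convolution oracle
  set.seed(22)
  cts <- rpois(200, 30)
  obj <- flat; obj$counts <- cts
  got <- ccg_baseline(obj, sigma_ms = 10)
  sb <- 20; half <- 100
  k <- dnorm(-half:half, sd = sb); k <- k / sum(k)
  xp <- c(cts[half:1], cts, cts[200:101])
  oracle <- vapply(1:200, function(i)
    sum(xp[(i):(i + 2 * half)] * k), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("detection applies the cumulative-Poisson two-consecutive-bin rule", {
  base_obj <- list(lag_s = seq(-0.05, 0.05, by = 5e-4)[-1] - 2.5e-4,
                   counts = rep(0L, 200), n_pre = 1, n_post = 1)
  class(base_obj) <- "ccg"
  ## a single significant bin is not enough
  one <- base_obj; one$counts[which.min(abs(one$lag_s - 0.00225))] <- 50L
  expect_null(detect_connection(one, baseline = rep(0.5, 200)))
  ## two consecutive bins above threshold are
  two <- one; two$counts[which.min(abs(two$lag_s - 0.00275))] <- 40L
  det <- detect_connection(two, baseline = rep(0.5, 200))
  expect_equal(det$latency_ms, 2.25, tolerance = 1e-9)
  expect_gt(det$excess, 0)
  ## threshold is strict: counts equal to qpois(0.999, base) do not fire
  thr <- qpois(0.999, 10)
  at <- base_obj; at$counts[101:108] <- as.integer(thr)
  expect_null(detect_connection(at, baseline = rep(10, 200)))
  above <- base_obj; above$counts[103:104] <- as.integer(thr + 1)
  expect_false(is.null(detect_connection(above, baseline = rep(10, 200))))
  ## bins outside (1, 5] ms are ignored
  outside <- base_obj; outside$counts[120:121] <- 100L  # ~9.75 ms
  expect_null(detect_connection(outside, baseline = rep(0.5, 200)))
})

test_that("injected transmission is detected; independent pairs are not", {
  cfg <- sim_config(duration = 1200, n_units = c(A = 1, B = 1),
                    tuning = list(frac_untuned = c(A = 1, B = 1),
                                  untuned_rate_range = c(15, 20)),
                    connections = data.frame(pre = 1, post = 1,
                                             latency_ms = 2.5, prob = 0.05,
                                             jitter_ms = 0.2))
  s <- simulate_session(cfg, seed = 61)
  ccg <- compute_ccg(s$spikes[["A1"]], s$spikes[["B1"]])
  det <- detect_connection(ccg)
  expect_false(is.null(det))
  expect_gte(det$latency_ms, 1)
  expect_lte(det$latency_ms, 5)
  ## detection is invariant under joint time translation
  ccg_t <- compute_ccg(s$spikes[["A1"]] + 500, s$spikes[["B1"]] + 500)
  expect_identical(ccg_t$counts, ccg$counts)
  ## independent pair: no detection
  set.seed(23)
  q1 <- sort(runif(12000, 0, 1200)); q2 <- sort(runif(12000, 0, 1200))
  expect_null(detect_connection(compute_ccg(q1, q2)))
})

test_that("sensitivity grows with transmission probability", {
  rate_at <- function(p, seeds) {
    mean(vapply(seeds, function(sd) {
      cfg <- sim_config(duration = 600, n_units = c(A = 1, B = 1),
                        tuning = list(frac_untuned = c(A = 1, B = 1),
                                      untuned_rate_range = c(15, 20)),
                        connections = data.frame(pre = 1, post = 1,
                                                 latency_ms = 2.5, prob = p,
                                                 jitter_ms = 0.2))
      s <- simulate_session(cfg, seed = sd)
      !is.null(detect_connection(compute_ccg(s$spikes[["A1"]], s$spikes[["B1"]])))
    }, logical(1)))
  }
  seeds <- 71:76
  expect_lte(rate_at(0, seeds), rate_at(0.03, seeds))
  expect_lte(rate_at(0.03, seeds), rate_at(0.2, seeds))
  expect_equal(rate_at(0.2, seeds), 1)
})

test_that("the census summarizes connected pairs and tolerates empty results", {
  cfg <- sim_config(duration = 400, n_units = c(A = 2, B = 2),
                    tuning = list(frac_untuned = c(A = 1, B = 1),
                                  untuned_rate_range = c(3, 5)))
  s <- simulate_session(cfg, seed = 62)
  hd_table <- data.frame(unit_id = s$units$unit_id, is_hd = FALSE,
                         pfd_deg = NA_real_)
  cen <- connection_census(s, hd_table)
  expect_s3_class(cen, "connection_census")
  expect_equal(nrow(cen$connections), 0)
  ## wired session: A->B connection appears with its pre/post labels
  cfg2 <- sim_config(duration = 900, n_units = c(A = 2, B = 2),
                     tuning = list(frac_untuned = c(A = 0, B = 0),
                                   kappa_range = c(4, 4), peak_range = c(40, 40)),
                     connections = data.frame(pre = 1, post = 2,
                                              latency_ms = 2, prob = 0.1,
                                              jitter_ms = 0.2))
  s2 <- simulate_session(cfg2, seed = 63)
  hd2 <- data.frame(unit_id = s2$units$unit_id, is_hd = TRUE,
                    pfd_deg = s2$truth$units$pfd)
  cen2 <- connection_census(s2, hd2)
  expect_true(any(cen2$connections$pre == "A1" & cen2$connections$post == "B2" &
                    cen2$connections$direction == "A->B"))
})
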