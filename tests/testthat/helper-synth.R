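## Shared fixtures, built in code.

th_centers <- seq(5, 355, by = 10)

## construct a tuning_curve object directly from rates/occupancy
make_tc <- function(rate, occupancy = rep(1, 36)) {
  structure(list(rate = rate, occupancy = occupancy,
                 counts = rate * occupancy, bin_centers = th_centers,
                 n_spikes = sum(rate * occupancy)),
            class = "tuning_curve")
}

## von Mises-shaped rate vector over the 36 bin centers
vm_rate <- function(pfd_deg, kappa, peak, base = 0) {
  d <- pi / 180 * (th_centers - pfd_deg)
  base + peak * exp(kappa * (cos(d) - 1))
}

## von Mises sampler (Best & Fisher rejection), degrees
rvonmises_deg <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- mu_deg + sign(u[3] - 0.5) * acos(f) * 180 / pi
    }
  }
  out %% 360
}

## small all-tuned two-region session for decoding/coordination tests
quick_session <- function(seed, duration = 360, nA = 20, nB = 20,
                          events = NULL, reference = list(),
                          kappa = c(4, 4), peak = c(40, 40)) {
  cfg <- sim_config(duration = duration, n_units = c(A = nA, B = nB),
                    events = events, reference = reference,
                    tuning = list(frac_untuned = c(A = 0, B = 0),
                                  kappa_range = kappa, peak_range = peak))
  simulate_session(cfg, seed = seed)
}

## reference dynamics switched off (rigid world-locked ensemble)
rigid_ref <- list(jitter_sd = 0, wobble_sd = 0, drift_sd_on = 0,
                  drift_sd_dark = 0)
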