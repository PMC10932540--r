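## Synthetic two-region head-direction session generator.
##
## One latent heading (an angular-velocity Ornstein-Uhlenbeck process)
## drives von Mises-tuned Poisson units in two regions ("A", thalamus-like;
## "B", cortex-like). Each region reads the heading through a reference
## offset that is shared between regions: it relaxes toward gain x magnitude
## after cue rotations, diffuses in darkness, and carries a small
## region-independent jitter. Spike transmission from A to B units can be
## injected at 1-5 ms latency, and each unit gets a mean waveform from an
## RS or FS template. Everything is reproducible from a single seed.

.merge_cfg <- function(defaults, user, path) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config entry '", path, "' must be a list")
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config key: ", path, "$", bad[1])
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

#' Simulation configuration for a synthetic two-region HD session
#'
#' Builds a validated configuration object. Defaults describe a realistic
#' freely-moving mouse session: ensembles of 20 (region A) and 30 (region B)
#' units, von Mises tuning with concentration 2-8 and peak rates 20-60 Hz,
#' heading driven by an angular-velocity Ornstein-Uhlenbeck process with
#' stationary SD 45 deg/s and relaxation 0.5 s, and a shared reference
#' offset that relaxes toward the cue over ~20 s after rotations and
#' diffuses in darkness.
#'
#' @param duration Session length in seconds.
#' @param n_units Named integer vector `c(A = , B = )`.
#' @param tuning List: `kappa_range`, `peak_range` (Hz), `baseline_range`
#'   (Hz), `untuned_rate_range` (Hz, rate of untuned units),
#'   `frac_untuned` (named per region).
#' @param heading List: `sigma_av` (deg/s, stationary SD of angular
#'   velocity), `tau_av` (s, AV relaxation), `init_deg` (start heading,
#'   `NULL` = random).
#' @param events Data frame with columns `time_s`, `event`
#'   (`rotate`/`cue_off`/`cue_on`) and `value` (rotation magnitude in
#'   degrees, one of +/-45, +/-90; ignored otherwise). Times strictly
#'   increasing; the session starts cue-on.
#' @param reference List: `relax_tau` (s, exponential relaxation of the
#'   offset toward the cue after rotation), `gain` (0-1, under-rotation),
#'   `jitter_sd` (deg, independent per-region offset jitter),
#'   `drift_sd_on` / `drift_sd_dark` (deg/sqrt(s), reference diffusion with
#'   cue on / off), `independent` (logical; `TRUE` gives each region its own
#'   reference realization), `lag_ms` (named per region; delays that
#'   region's reference trace).
#' @param connections Data frame `pre` (A unit index), `post` (B unit
#'   index), `latency_ms` in `[1, 5]`, `prob` in `[0, 1]`, `jitter_ms`.
#' @param waveforms List: `frac_fs` (named per region), `sample_rate` (Hz).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(duration = 600,
                       n_units = c(A = 20, B = 30),
                       tuning = list(),
                       heading = list(),
                       events = NULL,
                       reference = list(),
                       connections = NULL,
                       waveforms = list()) {
  cfg <- list(
    duration = duration,
    n_units = n_units,
    tuning = .merge_cfg(list(
      kappa_range = c(2, 8),
      peak_range = c(20, 60),
      baseline_range = c(0.5, 2),
      untuned_rate_range = c(1, 10),
      frac_untuned = c(A = 0.46, B = 0.88)
    ), tuning, "tuning"),
    heading = .merge_cfg(list(
      sigma_av = 45, tau_av = 0.5, init_deg = NULL
    ), heading, "heading"),
    events = if (is.null(events)) {
      data.frame(time_s = numeric(0), event = character(0), value = numeric(0))
    } else as.data.frame(events),
    reference = .merge_cfg(list(
      relax_tau = 20, gain = 1, jitter_sd = 1.5,
      wobble_sd = 10, wobble_tau = 0.5,
      drift_sd_on = 1.5, drift_sd_dark = 3.5,
      independent = FALSE, lag_ms = c(A = 0, B = 0)
    ), reference, "reference"),
    connections = if (is.null(connections)) {
      data.frame(pre = integer(0), post = integer(0), latency_ms = numeric(0),
                 prob = numeric(0), jitter_ms = numeric(0))
    } else as.data.frame(connections),
    waveforms = .merge_cfg(list(
      frac_fs = c(A = 0.1, B = 0.3), sample_rate = 30000
    ), waveforms, "waveforms")
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$duration), length(cfg$duration) == 1L)
  if (cfg$duration <= 0) stop("duration must be > 0")
  if (!all(c("A", "B") %in% names(cfg$n_units))) stop("n_units needs A and B")
  if (any(cfg$n_units < 0)) stop("negative unit count")
  if (any(cfg$tuning$kappa_range < 0)) stop("kappa must be >= 0")
  if (any(cfg$tuning$frac_untuned < 0 | cfg$tuning$frac_untuned > 1))
    stop("frac_untuned must be in [0, 1]")
  if (cfg$heading$sigma_av < 0 || cfg$heading$tau_av <= 0)
    stop("invalid heading dynamics")
  ev <- cfg$events
  if (nrow(ev)) {
    if (!all(c("time_s", "event", "value") %in% names(ev)))
      stop("events need time_s, event, value columns")
    if (any(diff(ev$time_s) <= 0)) stop("event times must be strictly increasing")
    if (!all(ev$event %in% c("rotate", "cue_off", "cue_on")))
      stop("unknown event type")
    if (any(ev$time_s <= 0 | ev$time_s >= cfg$duration))
      stop("event times must lie inside the session")
  }
  cn <- cfg$connections
  if (nrow(cn)) {
    if (any(cn$latency_ms < 1 | cn$latency_ms > 5))
      stop("transmission latency must be in [1, 5] ms")
    if (any(cn$prob < 0 | cn$prob > 1)) stop("transmission prob must be in [0, 1]")
  }
  if (cfg$reference$gain < 0 || cfg$reference$gain > 1)
    stop("rotation gain must be in [0, 1]")
  invisible(cfg)
}

#' Simulate the latent heading trajectory
#'
#' Angular velocity follows an Ornstein-Uhlenbeck process (exact
#' discretization at 1 ms) with stationary SD `sigma_av` and relaxation
#' `tau_av`; heading is its integral. Uses the current RNG state.
#'
#' @param cfg A [sim_config()].
#' @return List: `dt` (s), `av_deg_s` and `heading_deg` (1 kHz; heading
#'   unwrapped), and `tracking`, a 50 Hz data frame `time_s`, `hd_deg`
#'   (wrapped to `[0, 360)`).
#' @export
simulate_heading <- function(cfg) {
  n <- round(cfg$duration * 1000)
  dt <- 1e-3
  sig <- cfg$heading$sigma_av
  a <- exp(-dt / cfg$heading$tau_av)
  innov_sd <- sig * sqrt(1 - a^2)
  av0 <- if (sig > 0) stats::rnorm(1, 0, sig) else 0
  av <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                                 method = "recursive", init = av0))
  h0 <- if (is.null(cfg$heading$init_deg)) stats::runif(1, 0, 360) else cfg$heading$init_deg
  heading <- h0 + cumsum(av) * dt
  idx <- seq(1L, n, by = 20L)
  tracking <- data.frame(time_s = (idx - 1L) * dt,
                         hd_deg = heading[idx] %% 360)
  list(dt = dt, av_deg_s = av, heading_deg = heading, tracking = tracking)
}

## OU segment toward a fixed target, exact discretization
.ou_segment <- function(n, x0, target, tau, sigma, dt) {
  if (n == 0L) return(numeric(0))
  a <- exp(-dt / tau)
  innov_sd <- if (sigma > 0) sigma * sqrt(tau / 2) * sqrt(1 - a^2) else 0
  dev <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                                  method = "recursive", init = x0 - target))
  target + dev
}

## One realization of the shared reference trace over the event schedule.
.reference_trace <- function(cfg, n_ms) {
  dt <- 1e-3
  ref <- cfg$reference
  ev <- cfg$events
  bounds <- c(0, round(ev$time_s * 1000), n_ms)
  out <- numeric(n_ms)
  state_on <- TRUE
  target <- 0
  cur <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[k] + 1L
    i1 <- bounds[k + 1L]
    len <- i1 - i0 + 1L
    if (len > 0) {
      if (state_on) {
        seg <- .ou_segment(len, cur, target, ref$relax_tau, ref$drift_sd_on, dt)
      } else {
        seg <- cur + cumsum(stats::rnorm(len, 0, ref$drift_sd_dark * sqrt(dt)))
      }
      out[i0:i1] <- seg
      cur <- seg[len]
    }
    if (k <= nrow(ev)) {
      type <- ev$event[k]
      if (type == "rotate") target <- target + ref$gain * ev$value[k]
      else if (type == "cue_off") state_on <- FALSE
      else if (type == "cue_on") state_on <- TRUE
    }
  }
  out
}

#' Simulate per-region reference offsets
#'
#' The offset (in degrees) of each region's internal HD reference relative
#' to the world: shared relaxation toward the cue after rotations, shared
#' diffusion (stronger in darkness), plus small independent per-region
#' jitter. With `reference$independent = TRUE` each region gets its own
#' realization of the shared component. A per-region `lag_ms` delays that
#' region's trace.
#'
#' @param cfg A [sim_config()].
#' @param n_ms Number of 1 ms samples (defaults to the session duration).
#' @return List: `offset` (n_ms x 2 matrix, columns `A`, `B`), `shared`
#'   (the region-A shared trace), `cue_on` (logical per ms).
#' @export
simulate_offsets <- function(cfg, n_ms = round(cfg$duration * 1000)) {
  dt <- 1e-3
  ref <- cfg$reference
  ## shared component = slow reference dynamics (cue relaxation, darkness
  ## diffusion) plus a fast coherent wobble of the internal HD network
  wob <- function() {
    if (ref$wobble_sd <= 0) return(numeric(n_ms))
    .ou_segment(n_ms, 0, 0, ref$wobble_tau,
                ref$wobble_sd * sqrt(2 / ref$wobble_tau), dt)
  }
  shared_A <- .reference_trace(cfg, n_ms) + wob()
  shared_B <- if (isTRUE(ref$independent)) .reference_trace(cfg, n_ms) + wob() else shared_A
  jit <- function() {
    if (ref$jitter_sd <= 0) return(numeric(n_ms))
    .ou_segment(n_ms, 0, 0, 5, ref$jitter_sd * sqrt(2 / 5), dt)
  }
  off <- cbind(A = shared_A + jit(), B = shared_B + jit())
  lag <- ref$lag_ms
  for (r in c("A", "B")) {
    lr <- if (r %in% names(lag)) round(lag[[r]]) else 0
    if (lr > 0) off[, r] <- c(rep(off[1, r], lr), off[seq_len(n_ms - lr), r])
    else if (lr < 0) off[, r] <- c(off[(-lr + 1):n_ms, r], rep(off[n_ms, r], -lr))
  }
  ev <- cfg$events
  cue_on <- rep(TRUE, n_ms)
  if (nrow(ev)) {
    bounds <- c(round(ev$time_s * 1000), n_ms)
    on <- TRUE
    for (k in seq_len(nrow(ev))) {
      if (ev$event[k] == "cue_off") on <- FALSE
      else if (ev$event[k] == "cue_on") on <- TRUE
      i0 <- bounds[k] + 1L
      if (i0 <= n_ms) cue_on[i0:bounds[k + 1L]] <- on
    }
  }
  list(offset = off, shared = shared_A, cue_on = cue_on)
}

#' Simulate spike trains of von Mises-tuned Poisson units
#'
#' Unit i in region r fires as an inhomogeneous Poisson process with rate
#' `base + peak * exp(kappa * (cos(heading(t) - (pfd + offset_r(t))) - 1))`,
#' realized by per-millisecond Bernoulli thinning; spike times land on a
#' 0.1 ms sub-grid so that 0.5 ms cross-correlogram bins are meaningful.
#'
#' @param units Data frame with columns `region`, `pfd`, `kappa`, `peak`,
#'   `base` (untuned units have `peak = 0`).
#' @param heading_deg Unwrapped heading at 1 kHz.
#' @param offset n_ms x 2 matrix of per-region offsets (degrees).
#' @return Named list of strictly increasing spike-time vectors (seconds).
#' @export
simulate_spikes <- function(units, heading_deg, offset) {
  n <- length(heading_deg)
  out <- vector("list", nrow(units))
  names(out) <- rownames(units)
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    if (u$peak > 0) {
      delta <- deg2rad(heading_deg - (u$pfd + offset[, u$region]))
      lam <- u$base + u$peak * exp(u$kappa * (cos(delta) - 1))
    } else {
      lam <- rep(u$base, n)
    }
    p <- pmin(lam * 1e-3, 1)
    idx <- which(stats::runif(n) < p)
    out[[i]] <- (idx - 1L) * 1e-3 + sample.int(10L, length(idx), replace = TRUE) * 1e-4 - 1e-4
  }
  out
}

#' Inject spike transmission from a presynaptic into a postsynaptic train
#'
#' Each presynaptic spike elicits, with probability `prob`, one extra
#' postsynaptic spike at `latency_ms` plus Gaussian jitter. The result is
#' re-sorted and duplicate timestamps are dropped.
#'
#' @param pre,post Spike-time vectors (seconds).
#' @param prob Transmission probability in `[0, 1]`.
#' @param latency_ms Latency in `[1, 5]` ms.
#' @param jitter_ms SD of the latency jitter (ms).
#' @return Augmented postsynaptic train, with attribute `n_inserted`.
#' @export
inject_transmission <- function(pre, post, prob, latency_ms, jitter_ms = 0.2) {
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]")
  if (latency_ms < 1 || latency_ms > 5) stop("latency must be in [1, 5] ms")
  sel <- stats::runif(length(pre)) < prob
  new <- pre[sel] + latency_ms / 1000 +
    if (jitter_ms > 0) stats::rnorm(sum(sel), 0, jitter_ms / 1000) else 0
  out <- sort(c(post, new))
  if (length(out) > 1L) out <- out[c(TRUE, diff(out) > 0)]
  attr(out, "n_inserted") <- sum(sel)
  out
}

#' Synthetic mean spike waveform template
#'
#' A negative spike deflection (Gaussian trough) flanked by a small
#' pre-spike bump and an afterhyperpolarization bump peaking
#' `trough_to_peak_ms` after the trough. RS-like templates use a slow,
#' broad AHP; FS-like ones a fast, narrow AHP.
#'
#' @param trough_to_peak_ms Time from spike trough to AHP maximum (ms).
#' @param pre_amp,post_amp Amplitudes of the pre-spike and AHP bumps
#'   (relative to the unit trough).
#' @param spike_sd_ms,ahp_sd_ms Widths of trough and AHP (ms).
#' @param sample_rate Samples per second.
#' @param len_ms Template length (ms); the trough sits at 1 ms.
#' @return Numeric waveform vector.
#' @export
synth_waveform <- function(trough_to_peak_ms = 0.6, pre_amp = 0.15,
                           post_amp = 0.35, spike_sd_ms = 0.1,
                           ahp_sd_ms = 0.3, sample_rate = 30000,
                           len_ms = 3) {
  t <- seq(0, len_ms, by = 1000 / sample_rate)
  t0 <- 1
  pre_amp * exp(-(t - t0 + 0.3)^2 / (2 * 0.12^2)) -
    exp(-(t - t0)^2 / (2 * spike_sd_ms^2)) +
    post_amp * exp(-(t - t0 - trough_to_peak_ms)^2 / (2 * ahp_sd_ms^2))
}

#' Simulate per-unit mean waveforms
#'
#' Draws an RS or FS template for each unit according to the configured
#' fast-spiking fraction per region. RS templates have trough-to-AHP
#' durations above the 0.42 ms classification cutoff, FS templates below.
#'
#' @param cfg A [sim_config()].
#' @param regions Character vector of per-unit region labels.
#' @return List: `waveforms` (units x samples matrix), `class` (character
#'   vector, `"RS"`/`"FS"`), `sample_rate`.
#' @export
simulate_waveforms <- function(cfg, regions) {
  n <- length(regions)
  frac <- cfg$waveforms$frac_fs
  cls <- ifelse(stats::runif(n) < frac[regions], "FS", "RS")
  sr <- cfg$waveforms$sample_rate
  wf <- t(vapply(seq_len(n), function(i) {
    if (cls[i] == "RS") {
      synth_waveform(stats::runif(1, 0.55, 0.85), spike_sd_ms = 0.11,
                     ahp_sd_ms = stats::runif(1, 0.28, 0.40),
                     post_amp = stats::runif(1, 0.25, 0.45), sample_rate = sr)
    } else {
      synth_waveform(stats::runif(1, 0.18, 0.32), spike_sd_ms = 0.07,
                     ahp_sd_ms = stats::runif(1, 0.08, 0.14),
                     post_amp = stats::runif(1, 0.25, 0.45), sample_rate = sr)
    }
  }, numeric(length(synth_waveform(sample_rate = sr)))))
  list(waveforms = wf, class = unname(cls), sample_rate = sr)
}

#' Simulate a complete two-region HD session with ground truth
#'
#' Runs the full generative model under one seed: latent heading,
#' per-region reference offsets, tuned and untuned Poisson units, injected
#' A-to-B spike transmission, and mean waveforms. The returned session
#' carries the complete ground truth (latent series, unit parameters,
#' connection list, waveform classes) for validation.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds reproduce the session
#'   bit-identically.
#' @return Object of class `hd_session`: `units` (data frame), `spikes`
#'   (named list of spike-time vectors), `tracking` (50 Hz data frame),
#'   `events`, `waveforms`, `truth` (latent heading/AV/offsets at 1 kHz,
#'   unit parameters, connections, waveform classes), `config`, `seed`.
#' @export
simulate_session <- function(cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  set.seed(seed)
  hd <- simulate_heading(cfg)
  n_ms <- length(hd$heading_deg)
  offs <- simulate_offsets(cfg, n_ms)

  nA <- cfg$n_units[["A"]]
  nB <- cfg$n_units[["B"]]
  region <- c(rep("A", nA), rep("B", nB))
  ids <- c(if (nA) paste0("A", seq_len(nA)), if (nB) paste0("B", seq_len(nB)))
  tun <- cfg$tuning
  tuned <- stats::runif(nA + nB) >= tun$frac_untuned[region]
  units <- data.frame(
    unit_id = ids, region = region, tuned = tuned,
    pfd = stats::runif(nA + nB, 0, 360),
    kappa = ifelse(tuned, stats::runif(nA + nB, tun$kappa_range[1], tun$kappa_range[2]), 0),
    peak = ifelse(tuned, stats::runif(nA + nB, tun$peak_range[1], tun$peak_range[2]), 0),
    base = ifelse(tuned,
                  stats::runif(nA + nB, tun$baseline_range[1], tun$baseline_range[2]),
                  stats::runif(nA + nB, tun$untuned_rate_range[1], tun$untuned_rate_range[2])),
    row.names = ids
  )
  spikes <- simulate_spikes(units, hd$heading_deg, offs$offset)

  cn <- cfg$connections
  if (nrow(cn)) {
    for (k in seq_len(nrow(cn))) {
      pre_id <- paste0("A", cn$pre[k])
      post_id <- paste0("B", cn$post[k])
      spikes[[post_id]] <- inject_transmission(spikes[[pre_id]], spikes[[post_id]],
                                               cn$prob[k], cn$latency_ms[k],
                                               cn$jitter_ms[k])
    }
  }
  wf <- simulate_waveforms(cfg, region)

  structure(list(
    units = units[, c("unit_id", "region")],
    spikes = spikes,
    tracking = hd$tracking,
    events = cfg$events,
    waveforms = wf$waveforms,
    wf_sample_rate = wf$sample_rate,
    truth = list(
      heading_deg = hd$heading_deg, av_deg_s = hd$av_deg_s,
      offset = offs$offset, cue_on = offs$cue_on,
      units = units, connections = cn, wf_class = wf$class
    ),
    config = cfg, seed = seed
  ), class = "hd_session")
}

#' @export
print.hd_session <- function(x, ...) {
  cat("<hd_session>", sum(x$units$region == "A"), "region-A units,",
      sum(x$units$region == "B"), "region-B units,",
      sprintf("%.1f min", max(x$tracking$time_s) / 60), "\n")
  if (nrow(x$events)) {
    cat("  events:", paste(sprintf("%s@%.0fs", x$events$event, x$events$time_s),
                           collapse = ", "), "\n")
  }
  cat("  total spikes:", sum(lengths(x$spikes)), "\n")
  invisible(x)
}
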