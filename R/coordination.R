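## Coordination of the two regions' HD representations: cue-rotation
## realignment of preferred directions, inter-regional lag analysis of
## decoded errors, and darkness drift correlation.

#' Per-unit preferred-direction shifts across a rotation trial
#'
#' Computes each unit's PFD from smoothed tuning curves in the pre- and
#' post-rotation windows and returns the wrapped shift. Units are dropped
#' (NA) when any heading bin has less than `min_occ_s` occupancy in either
#' window, mirroring the 1 s minimum-occupancy inclusion rule.
#'
#' @param session An `hd_session`.
#' @param unit_ids Units to evaluate (e.g. the HD cells of one region).
#' @param pre_window,post_window `c(start, end)` seconds.
#' @param min_occ_s Per-bin minimum occupancy (s); 0 disables the gate.
#' @param sigma_bins Smoothing SD (bins).
#' @return Named vector of PFD shifts (deg, post minus pre, wrapped).
#' @export
pfd_shifts <- function(session, unit_ids, pre_window, post_window,
                       min_occ_s = 1, sigma_bins = 1) {
  vapply(unit_ids, function(id) {
    tcs <- lapply(list(pre_window, post_window), function(w) {
      compute_tuning_curve(session$spikes[[id]], session$tracking, rbind(w))
    })
    if (min_occ_s > 0 &&
        any(vapply(tcs, function(tc) any(tc$occupancy < min_occ_s), logical(1))))
      return(NA_real_)
    if (any(vapply(tcs, function(tc) tc$n_spikes == 0, logical(1))))
      return(NA_real_)
    pfds <- vapply(tcs, function(tc)
      resultant_and_pfd(smooth_tuning_curve(tc, sigma_bins))$pfd_deg, numeric(1))
    wrap_diff(pfds[2], pfds[1])
  }, numeric(1))
}

#' Ensemble rotation: circular mean of per-unit PFD shifts
#'
#' @param shifts Per-unit PFD shifts in degrees (NAs dropped).
#' @return List `mean_deg`, `sem_deg` (circular SD / sqrt(n)), `n`.
#' @export
ensemble_rotation <- function(shifts) {
  shifts <- shifts[!is.na(shifts)]
  if (length(shifts) < 2L) stop("need at least 2 HD units with defined shifts")
  m <- circ_mean_resultant(shifts)
  list(mean_deg = m$mean_deg, sem_deg = circ_sd_deg(m$R) / sqrt(length(shifts)),
       n = length(shifts))
}

#' Rigidity of pairwise PFD differences across a rotation
#'
#' Circular correlation between the pairwise PFD differences of all unique
#' unit pairs before versus after a cue rotation. A coherently rotating
#' ensemble keeps its internal PFD geometry, giving correlations near 1.
#'
#' @param pre_pfds,post_pfds Per-unit PFDs (deg) before and after.
#' @return Fisher-Lee circular correlation of the pair differences.
#' @export
pair_rigidity <- function(pre_pfds, post_pfds) {
  ok <- !is.na(pre_pfds) & !is.na(post_pfds)
  pre <- pre_pfds[ok]; post <- post_pfds[ok]
  if (length(pre) < 3L) stop("need at least 3 units")
  pr <- utils::combn(length(pre), 2)
  d_pre <- wrap_diff(pre[pr[1, ]], pre[pr[2, ]])
  d_post <- wrap_diff(post[pr[1, ]], post[pr[2, ]])
  circ_corr(d_pre, d_post)
}

#' Significance of an ensemble rotation by index reassignment
#'
#' Builds, for each unit, a null distribution of PFD-shift magnitudes by
#' randomly reassigning the tracking-sample indices of the pre and post
#' windows 500 times (the same reassignments for all units) and recomputing
#' the shift. The trial is significant if at least half of the units
#' exceed their own 98th-percentile null magnitude (boundary inclusive).
#'
#' @param session An `hd_session`.
#' @param unit_ids Units entering the test.
#' @param pre_window,post_window Trial windows (s).
#' @param n Number of reassignments.
#' @param prob Null percentile.
#' @return List: `significant`, `frac_exceeding`, `per_unit` data frame
#'   (`shift_deg`, `null_thr_deg`, `exceeds`).
#' @export
rotation_significance <- function(session, unit_ids, pre_window, post_window,
                                  n = 500, prob = 0.98) {
  tr <- session$tracking
  pre_keep <- .tracking_mask(tr, rbind(pre_window))
  post_keep <- .tracking_mask(tr, rbind(post_window))
  all_idx <- which(pre_keep | post_keep)
  n_pre <- sum(pre_keep)
  bins <- .hd_bins(tr$hd_deg)[all_idx]
  m <- length(all_idx)
  zc <- exp(1i * deg2rad(seq(5, 355, by = 10)))

  pfd_of <- function(cnt, occ) {
    sc <- .circ_gauss_smooth(cnt, 1); so <- .circ_gauss_smooth(occ, 1)
    r <- ifelse(so > 1e-12, pmax(sc, 0) / so, 0)
    (Arg(sum(r * zc)) * 180 / pi) %% 360
  }

  ## per-unit: pooled-sample ordinal and HD bin of every spike
  unit_spk <- lapply(unit_ids, function(id) {
    si <- .spike_samples(session$spikes[[id]], tr)
    pos <- match(si[!is.na(si)], all_idx)
    pos <- pos[!is.na(pos)]
    list(pos = pos, bin = bins[pos], all = tabulate(bins[pos], TC_NBINS))
  })
  names(unit_spk) <- unit_ids

  occ_all <- tabulate(bins, TC_NBINS)
  real_shift <- abs(pfd_shifts(session, unit_ids, pre_window, post_window,
                               min_occ_s = 0))

  null_mag <- matrix(NA_real_, n, length(unit_ids))
  for (r in seq_len(n)) {
    fake_pre <- logical(m)
    fake_pre[sample.int(m, n_pre)] <- TRUE
    occ_pre <- tabulate(bins[fake_pre], TC_NBINS)
    occ_post <- occ_all - occ_pre
    for (j in seq_along(unit_ids)) {
      u <- unit_spk[[j]]
      sel <- fake_pre[u$pos]
      c_pre <- tabulate(u$bin[sel], TC_NBINS)
      c_post <- u$all - c_pre
      if (sum(c_pre) == 0 || sum(c_post) == 0) next
      p1 <- pfd_of(c_pre, occ_pre)
      p2 <- pfd_of(c_post, occ_post)
      null_mag[r, j] <- abs(wrap_diff(p2, p1))
    }
  }
  thr <- apply(null_mag, 2, stats::quantile, probs = prob, na.rm = TRUE, names = FALSE)
  exceeds <- !is.na(real_shift) & real_shift > thr
  frac <- mean(exceeds)
  list(significant = frac >= 0.5, frac_exceeding = frac,
       per_unit = data.frame(unit_id = unit_ids, shift_deg = real_shift,
                             null_thr_deg = thr, exceeds = exceeds))
}

#' Inclusion rule for post-rotation lag analyses
#'
#' Cue-rotation trials enter the inter-regional lag analysis only when the
#' ensemble actually realigned: the absolute mean rotation must be at
#' least 17.2 degrees.
#'
#' @param mean_rotation_deg Ensemble mean rotation(s), degrees.
#' @param min_shift_deg Inclusion threshold.
#' @return Logical vector.
#' @export
trial_inclusion <- function(mean_rotation_deg, min_shift_deg = 17.2) {
  abs(mean_rotation_deg) >= min_shift_deg
}

#' Running circular median smoothing of a decoded-error trace
#'
#' Median over a centered 5 s window of the unwrapped error, truncated at
#' the edges, then re-wrapped.
#'
#' @param error_deg Error trace on a uniform 20 ms grid.
#' @param window_s Window length (s).
#' @param dt Grid step (s).
#' @return Smoothed error (deg, wrapped).
#' @export
smooth_error <- function(error_deg, window_s = 5, dt = 0.02) {
  u <- unwrap_deg(error_deg)
  h <- floor(window_s / dt / 2)
  n <- length(u)
  out <- vapply(seq_len(n), function(i) {
    stats::median(u[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  wrap_deg(out)
}

## Pearson correlation between x and y at all lags in [-L, L] bins, with
## truncated overlap; per-lag means and SDs via cumulative sums, the
## cross-products via FFT convolution.
.xcorr_pearson <- function(x, y, L) {
  n <- length(x)
  ## conv(x, rev(y))[s] = sum_i x[i] y[i + (n - s)], so the lagged cross
  ## product sum_i x[i] y[i + l] sits at index n - l
  cc <- stats::convolve(x, y, type = "open")
  lags <- -L:L
  sxy <- cc[n - lags]
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  r <- numeric(length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    m <- n - abs(l)
    if (l >= 0) {  # pairs x[1:(n-l)], y[(1+l):n]
      sx <- cx[m]; sx2 <- cx2[m]
      sy <- cy[n] - if (l > 0) cy[l] else 0
      sy2 <- cy2[n] - if (l > 0) cy2[l] else 0
    } else {
      sx <- cx[n] - cx[-l]; sx2 <- cx2[n] - cx2[-l]
      sy <- cy[m]; sy2 <- cy2[m]
    }
    num <- sxy[k] - sx * sy / m
    den <- sqrt(max(sx2 - sx^2 / m, 0) * max(sy2 - sy^2 / m, 0))
    r[k] <- if (den > 0) num / den else NA_real_
  }
  r
}

## verify the FFT cross-product orientation once at load time would be
## overkill; covered by unit tests instead.

#' Temporal cross-correlation of paired decoded errors
#'
#' Pearson cross-correlation between the two regions' decoded-error traces
#' (unwrapped within the window, mean-removed, truncated overlap) over lags
#' of +/- `max_lag_s` in 20 ms steps. Positive lag means region A leads.
#' The peak lag is the argmax (ties: smallest `|lag|`, then negative). A
#' null peak-lag distribution is built from `n_null` random circular
#' shifts of the region-B trace.
#'
#' @param errA,errB Decoded-error traces (deg) on a common uniform 20 ms
#'   grid, e.g. a 75 s or 25 s window.
#' @param dt Grid step (s).
#' @param max_lag_s Maximum lag (s).
#' @param n_null Number of circular-shift null samples (0 to skip).
#' @param min_shift_s Minimum null shift (s).
#' @return Object of class `lag_result`: `lag_s`, `corr`, `peak_lag_s`,
#'   `peak_corr`, `null_peak_lag_s`.
#' @export
error_crosscorr <- function(errA, errB, dt = 0.02, max_lag_s = 5,
                            n_null = 100, min_shift_s = 10) {
  n <- length(errA)
  if (length(errB) != n) stop("trace length mismatch")
  L <- round(max_lag_s / dt)
  if (n <= L + 2) stop("window shorter than the maximum lag")
  x <- unwrap_deg(errA); x <- x - mean(x)
  y <- unwrap_deg(errB); y <- y - mean(y)
  lags <- (-L:L) * dt
  r <- .xcorr_pearson(x, y, L)
  peak <- .peak_lag(r, lags)

  null_peaks <- numeric(0)
  if (n_null > 0) {
    min_b <- min(max(1L, round(min_shift_s / dt)), floor(n / 3))
    null_peaks <- vapply(seq_len(n_null), function(i) {
      k <- sample((min_b):(n - min_b), 1)
      ys <- y[c((k + 1):n, 1:k)]
      .peak_lag(.xcorr_pearson(x, ys - mean(ys), L), lags)["lag"]
    }, numeric(1))
  }
  structure(list(lag_s = lags, corr = r, peak_lag_s = unname(peak["lag"]),
                 peak_corr = unname(peak["corr"]),
                 null_peak_lag_s = unname(null_peaks)),
            class = "lag_result")
}

.peak_lag <- function(r, lags) {
  mx <- max(r, na.rm = TRUE)
  cand <- which(r >= mx - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  c(lag = lags[cand[1]], corr = r[cand[1]])
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> peak corr %.3f at lag %+.0f ms (%d null shifts)\n",
              x$peak_corr, x$peak_lag_s * 1000, length(x$null_peak_lag_s)))
  invisible(x)
}

#' Kolmogorov-Smirnov test of peak lags against a shift null
#'
#' Two-sample KS test between the observed peak-lag distribution (across
#' trials) and the pooled circular-shift null.
#'
#' @param real_lags Observed peak lags (s), one per trial.
#' @param null_lags Pooled null peak lags (s).
#' @return An `htest` object.
#' @export
peak_lag_ks <- function(real_lags, null_lags) {
  suppressWarnings(stats::ks.test(real_lags, null_lags, exact = FALSE))
}

#' Lagged difference profile between two decoded traces
#'
#' For each lag, the wrapped difference between the region-A trace and the
#' lag-shifted region-B trace is summarized as the median of the absolute
#' per-segment medians over 7 non-overlapping 5 s segments (35 s total);
#' the trough lag of the profile marks the temporal offset between the two
#' representations.
#'
#' @param decA,decB Decoded traces (deg) on a common uniform 20 ms grid;
#'   must cover at least 35 s plus two maximum lags.
#' @param dt Grid step (s).
#' @param max_lag_s Maximum lag (s).
#' @param seg_s Segment length (s).
#' @param n_seg Number of segments.
#' @return List: `lag_s`, `profile_deg`, `trough_lag_s`.
#' @export
difference_profile <- function(decA, decB, dt = 0.02, max_lag_s = 5,
                               seg_s = 5, n_seg = 7) {
  n <- length(decA)
  if (length(decB) != n) stop("trace length mismatch")
  L <- round(max_lag_s / dt)
  spb <- round(seg_s / dt)
  need <- n_seg * spb
  if (n < need + 2 * L) stop("need at least 35 s plus lag margins of data")
  i0 <- L + 1
  seg_id <- rep(seq_len(n_seg), each = spb)
  ai <- i0:(i0 + need - 1)
  lags <- (-L:L) * dt
  prof <- vapply(-L:L, function(l) {
    d <- wrap_diff(decA[ai], decB[ai + l])
    segm <- vapply(split(d, seg_id), stats::median, numeric(1))
    stats::median(abs(segm))
  }, numeric(1))
  tr <- which(prof <= min(prof) + 1e-12)
  tr <- tr[order(abs(lags[tr]), lags[tr])][1]
  list(lag_s = lags, profile_deg = prof, trough_lag_s = lags[tr])
}

## --- darkness drift --------------------------------------------------------

## cue state per arbitrary time from the event schedule (TRUE = cue on)
cue_state_at <- function(events, times) {
  on <- rep(TRUE, length(times))
  if (!nrow(events)) return(on)
  state <- TRUE
  bounds <- c(-Inf, events$time_s, Inf)
  for (k in seq_len(nrow(events) + 1L)) {
    sel <- times >= bounds[k] & times < bounds[k + 1L]
    on[sel] <- state
    if (k <= nrow(events)) {
      if (events$event[k] == "cue_off") state <- FALSE
      else if (events$event[k] == "cue_on") state <- TRUE
    }
  }
  on
}

#' Drift analysis of paired decoded errors across cue states
#'
#' Averages each region's decoded error over 2-minute bins (bins never
#' straddle a cue on/off change), yielding paired drift series, and
#' quantifies inter-regional coordination as the circular correlation of
#' the two series -- overall, per cue state, and per angular-velocity
#' state (median |AV| within the bin against a 30 deg/s cutoff computed
#' sample-wise). A null band comes from `n_null` circular shifts of the
#' region-B series. Also returns the column-normalized 2-D histogram of
#' paired drifts (columns = region-A bins).
#'
#' @param trajA,trajB `decoded_trajectory` objects on a common grid.
#' @param events Event schedule data frame.
#' @param tracking 50 Hz tracking (for angular velocity).
#' @param window Optional `c(start, end)` restricting the analysis (s),
#'   e.g. the post-training period.
#' @param bin_s Drift bin length (s).
#' @param av_cut AV cutoff (deg/s).
#' @param n_null Number of circular-shift null correlations.
#' @param hist_bin_deg 2-D histogram bin width (deg).
#' @return Object of class `drift_result`: `bins` data frame (`t0`, `t1`,
#'   `cue_on`, `driftA_deg`, `driftB_deg`, `av_high`, plus low/high-AV
#'   drift columns), `corr` (overall/cue_on/cue_off and AV splits), `null`
#'   (per-scope null correlation vectors), `hist2d`.
#' @export
drift_analysis <- function(trajA, trajB, events, tracking, window = NULL,
                           bin_s = 120, av_cut = 30, n_null = 100,
                           hist_bin_deg = 10) {
  stopifnot(nrow(trajA) == nrow(trajB))
  times <- trajA$time_s
  keep <- rep(TRUE, length(times))
  if (!is.null(window)) keep <- times >= window[1] & times < window[2]
  av <- stats::approx(tracking$time_s, angular_velocity(tracking),
                      xout = times, rule = 2)$y

  on <- cue_state_at(events, times)
  ## maximal same-state runs, chopped into full bins
  run <- cumsum(c(TRUE, diff(on) != 0) | c(TRUE, diff(keep) != 0))
  run[!keep] <- NA
  bins <- list()
  dt <- times[2] - times[1]
  per_bin <- round(bin_s / dt)
  for (rr in unique(run[!is.na(run)])) {
    idx <- which(run == rr & keep)
    nfull <- length(idx) %/% per_bin
    if (nfull == 0) next
    for (b in seq_len(nfull)) {
      ii <- idx[((b - 1) * per_bin + 1):(b * per_bin)]
      eA <- trajA$error_deg[ii]; eB <- trajB$error_deg[ii]
      hi <- abs(av[ii]) > av_cut
      cm <- function(e, sel) {
        e <- e[sel & !is.na(e)]
        if (length(e) < per_bin / 10) NA_real_ else circ_mean_resultant(e)$mean_deg
      }
      bins[[length(bins) + 1L]] <- data.frame(
        t0 = times[ii[1]], t1 = times[ii[length(ii)]] + dt,
        cue_on = on[ii[1]],
        driftA_deg = cm(eA, TRUE), driftB_deg = cm(eB, TRUE),
        driftA_lo = cm(eA, !hi), driftB_lo = cm(eB, !hi),
        driftA_hi = cm(eA, hi), driftB_hi = cm(eB, hi),
        av_high = stats::median(abs(av[ii])) > av_cut)
    }
  }
  bins <- do.call(rbind, bins)
  if (is.null(bins) || nrow(bins) < 3)
    stop("fewer than 3 complete drift bins")

  corr_of <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) return(NA_real_)
    tryCatch(circ_corr(a[ok], b[ok]), error = function(e) NA_real_)
  }
  scopes <- list(
    overall = rep(TRUE, nrow(bins)),
    cue_on = bins$cue_on, cue_off = !bins$cue_on
  )
  corr <- c(
    vapply(scopes, function(s) corr_of(bins$driftA_deg[s], bins$driftB_deg[s]),
           numeric(1)),
    cue_on_lowAV = corr_of(bins$driftA_lo[bins$cue_on], bins$driftB_lo[bins$cue_on]),
    cue_on_highAV = corr_of(bins$driftA_hi[bins$cue_on], bins$driftB_hi[bins$cue_on]),
    cue_off_lowAV = corr_of(bins$driftA_lo[!bins$cue_on], bins$driftB_lo[!bins$cue_on]),
    cue_off_highAV = corr_of(bins$driftA_hi[!bins$cue_on], bins$driftB_hi[!bins$cue_on])
  )
  null <- lapply(scopes, function(s) {
    a <- bins$driftA_deg[s]; b <- bins$driftB_deg[s]
    nb <- length(b)
    if (nb < 4 || n_null == 0) return(numeric(0))
    vapply(seq_len(n_null), function(i) {
      k <- sample(nb - 1L, 1L)
      corr_of(a, b[c((k + 1):nb, 1:k)])
    }, numeric(1))
  })

  brks <- seq(-180, 180, by = hist_bin_deg)
  ok <- !is.na(bins$driftA_deg) & !is.na(bins$driftB_deg)
  h <- table(cut(bins$driftB_deg[ok], brks), cut(bins$driftA_deg[ok], brks))
  h <- unclass(h)
  cm <- apply(h, 2, max)
  h <- sweep(h, 2, pmax(cm, 1), "/")

  structure(list(bins = bins, corr = corr, null = null, hist2d = h),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat("<drift_result>", nrow(x$bins), "bins;",
      sum(x$bins$cue_on), "cue-on,", sum(!x$bins$cue_on), "cue-off\n")
  print(round(x$corr, 3))
  invisible(x)
}

#' Ensemble tuning-curve drift over 2-minute bins
#'
#' Mean PFD of an ensemble evaluated in consecutive 2-minute bins (within
#' same-cue-state runs); drift is each bin's wrapped deviation from the
#' session's first cue-on bin.
#'
#' @param session An `hd_session`.
#' @param unit_ids Ensemble units (HD cells).
#' @param bin_s Bin length (s).
#' @param window Optional analysis window (s).
#' @return Data frame `t0`, `t1`, `cue_on`, `pfd_drift_deg`.
#' @export
ensemble_pfd_drift <- function(session, unit_ids, bin_s = 120, window = NULL) {
  tr <- session$tracking
  times <- tr$time_s
  keep <- if (is.null(window)) rep(TRUE, length(times)) else
    times >= window[1] & times < window[2]
  on <- cue_state_at(session$events, times)
  run <- cumsum(c(TRUE, diff(on) != 0))
  dt <- times[2] - times[1]
  per_bin <- round(bin_s / dt)
  rows <- list()
  for (rr in unique(run[keep])) {
    idx <- which(run == rr & keep)
    nfull <- length(idx) %/% per_bin
    for (b in seq_len(nfull)) {
      ii <- idx[((b - 1) * per_bin + 1):(b * per_bin)]
      w <- rbind(c(times[ii[1]], times[ii[length(ii)]] + dt))
      shifts <- vapply(unit_ids, function(id) {
        tc <- tryCatch(compute_tuning_curve(session$spikes[[id]], tr, w),
                       error = function(e) NULL)
        if (is.null(tc) || tc$n_spikes < 10) return(NA_real_)
        resultant_and_pfd(smooth_tuning_curve(tc))$pfd_deg
      }, numeric(1))
      if (all(is.na(shifts))) next
      m <- circ_mean_resultant(shifts[!is.na(shifts)])$mean_deg
      rows[[length(rows) + 1L]] <- data.frame(
        t0 = w[1], t1 = w[2], cue_on = on[ii[1]], pfd_mean_deg = m)
    }
  }
  out <- do.call(rbind, rows)
  ref <- out$pfd_mean_deg[which(out$cue_on)[1]]
  out$pfd_drift_deg <- wrap_diff(out$pfd_mean_deg, ref)
  out
}
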