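## Tuning curves, HD metrics and shuffle-based HD-cell classification.
##
## A tuning curve is the spike histogram over 36 half-open 10-degree
## heading bins ([0,10), [10,20), ...; centers 5, 15, ...) divided by the
## occupancy. Spikes are assigned to the nearest 50 Hz tracking sample.

TC_NBINS <- 36L
TC_BINW <- 10

## logical mask over tracking samples from an intervals matrix/data.frame
## (start, end) or a logical vector
.tracking_mask <- function(tracking, mask) {
  n <- nrow(tracking)
  if (is.null(mask)) return(rep(TRUE, n))
  if (is.logical(mask)) {
    if (length(mask) != n) stop("logical mask length mismatch")
    return(mask)
  }
  iv <- matrix(as.numeric(as.matrix(mask)), ncol = 2)
  out <- rep(FALSE, n)
  t <- tracking$time_s
  for (k in seq_len(nrow(iv)))
    out <- out | (t >= iv[k, 1] & t < iv[k, 2])
  out
}

## map spike times to tracking-sample indices (nearest sample); NA outside
.spike_samples <- function(spike_times, tracking) {
  t0 <- tracking$time_s[1]
  dt <- tracking$time_s[2] - tracking$time_s[1]
  idx <- round((spike_times - t0) / dt) + 1
  idx[idx < 1 | idx > nrow(tracking)] <- NA
  idx
}

.hd_bins <- function(hd_deg) {
  b <- floor((hd_deg %% 360) / TC_BINW) + 1L
  b[b > TC_NBINS] <- TC_NBINS  # guard hd == 360 after float wrap
  b
}

#' Occupancy-normalized HD tuning curve
#'
#' Histogram of spikes over 36 x 10-degree heading bins divided by the
#' occupancy (seconds spent per bin at the 50 Hz tracking resolution).
#' Spikes are assigned the heading of their nearest tracking sample, so
#' the count accounting is exact: `sum(rate * occupancy)` equals the
#' number of spikes used. Bins with zero occupancy get `NA` rates.
#'
#' @param spike_times Spike times (s).
#' @param tracking Data frame `time_s`, `hd_deg` at uniform 50 Hz.
#' @param mask Optional analysis mask: a two-column matrix/data frame of
#'   `(start, end)` intervals in seconds, or a logical vector over tracking
#'   samples.
#' @return Object of class `tuning_curve`: `rate` (Hz), `occupancy` (s),
#'   `counts`, `bin_centers` (deg), `n_spikes`.
#' @export
compute_tuning_curve <- function(spike_times, tracking, mask = NULL) {
  keep <- .tracking_mask(tracking, mask)
  if (!any(keep)) stop("empty mask: no tracking samples selected")
  dt <- tracking$time_s[2] - tracking$time_s[1]
  bins <- .hd_bins(tracking$hd_deg)
  occ <- tabulate(bins[keep], TC_NBINS) * dt
  si <- .spike_samples(spike_times, tracking)
  si <- si[!is.na(si)]
  si <- si[keep[si]]
  counts <- tabulate(bins[si], TC_NBINS)
  rate <- ifelse(occ > 0, counts / occ, NA_real_)
  structure(list(rate = rate, occupancy = occ, counts = counts,
                 bin_centers = seq(TC_BINW / 2, 360 - TC_BINW / 2, by = TC_BINW),
                 n_spikes = length(si)),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("<tuning_curve> ", x$n_spikes, " spikes over ",
      sprintf("%.1f", sum(x$occupancy)), " s; mean rate ",
      sprintf("%.2f", x$n_spikes / sum(x$occupancy)), " Hz, peak ",
      sprintf("%.2f", max(x$rate, na.rm = TRUE)), " Hz\n", sep = "")
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$bin_centers, x$rate, type = "h", lwd = 3,
                 xlab = "head direction (deg)", ylab = "rate (Hz)", ...)
  invisible(x)
}

## Circular Gaussian smoothing of a 36-vector, defined in the Fourier
## domain (coefficients exp(-(k*sigma_theta)^2/2)) so that the Gaussian
## semigroup holds exactly: smoothing twice with sigma equals once with
## sigma*sqrt(2).
.circ_gauss_smooth <- function(v, sigma_bins) {
  n <- length(v)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  kf <- exp(-0.5 * (k * sigma_bins * 2 * pi / n)^2)
  out <- Re(stats::fft(stats::fft(v) * kf, inverse = TRUE)) / n
  out[abs(out) < 1e-12] <- 0
  out
}

#' Smooth a tuning curve with a circular Gaussian kernel
#'
#' Counts and occupancy are smoothed separately (spectral circular
#' Gaussian, default SD of one 10-degree bin) and re-divided, which
#' preserves the total spike mass: `sum(rate * occupancy)` is unchanged
#' to numerical precision.
#'
#' @param tc A [compute_tuning_curve()] result.
#' @param sigma_bins Kernel SD in bins (1 bin = 10 degrees).
#' @return A smoothed `tuning_curve`.
#' @export
smooth_tuning_curve <- function(tc, sigma_bins = 1) {
  sc <- .circ_gauss_smooth(tc$counts, sigma_bins)
  so <- .circ_gauss_smooth(tc$occupancy, sigma_bins)
  rate <- ifelse(so > 0, sc / so, NA_real_)
  structure(list(rate = rate, occupancy = so, counts = sc,
                 bin_centers = tc$bin_centers, n_spikes = tc$n_spikes),
            class = "tuning_curve")
}

#' Directional information of a tuning curve (bits/spike)
#'
#' \deqn{I = \sum_i \frac{\lambda(x_i)}{\lambda}
#'   \log_2\frac{\lambda(x_i)}{\lambda} \, p(x_i)}
#' where `p(x_i)` is the occupancy fraction of bin i, `lambda(x_i)` its
#' rate and `lambda` the occupancy-weighted mean rate. Zero-rate bins
#' contribute 0; zero-occupancy bins are excluded.
#'
#' @param tc A `tuning_curve`.
#' @return Information in bits/spike (>= 0).
#' @export
directional_information <- function(tc) {
  ok <- tc$occupancy > 0
  p <- tc$occupancy[ok] / sum(tc$occupancy[ok])
  lam <- tc$rate[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) stop("zero mean rate")
  rel <- lam / lbar
  sum(ifelse(rel > 0, rel * log2(rel) * p, 0))
}

#' Resultant length and preferred firing direction of a tuning curve
#'
#' Rate-weighted circular mean over bin centers: the mean direction is the
#' preferred firing direction (PFD), the resultant length R measures
#' tuning sharpness.
#'
#' @param tc A `tuning_curve`.
#' @return List `R`, `pfd_deg` (in `[0, 360)`).
#' @export
resultant_and_pfd <- function(tc) {
  ok <- tc$occupancy > 0 & !is.na(tc$rate)
  w <- pmax(tc$rate[ok], 0)  # spectral smoothing can leave tiny ringing
  if (sum(w) <= 0) stop("all-zero tuning curve")
  m <- circ_mean_resultant(tc$bin_centers[ok], w = w)
  list(R = m$R, pfd_deg = m$mean_deg %% 360)
}

#' von Mises concentration implied by a (smoothed) tuning curve
#'
#' Concentration kappa obtained by inverting the von Mises A1 function at
#' the rate-weighted resultant length of the curve.
#'
#' @param tc A `tuning_curve` (normally smoothed).
#' @return Concentration parameter (>= 0).
#' @export
tc_concentration <- function(tc) {
  kappa_from_R(resultant_and_pfd(tc)$R)
}

## --- circular peak finding -------------------------------------------------

## Peaks on a circular curve under the joint constraints used for HD-cell
## peak counting: minimum circular peak distance 120 deg, minimum width
## 40 deg (at half prominence), prominence > 11 Hz.
#' Find peaks of a circular tuning curve
#'
#' Local maxima of the (smoothed) curve on the circle, with prominence
#' computed circularly, width measured at half prominence, and taller
#' peaks suppressing smaller ones closer than the minimum circular
#' distance.
#'
#' @param tc A smoothed `tuning_curve`.
#' @param min_distance_deg Minimum circular distance between peaks.
#' @param min_width_deg Minimum width at half prominence.
#' @param min_prominence Minimum prominence (Hz, strict).
#' @return Data frame `location_deg`, `height`, `prominence`, `width_deg`,
#'   ordered by height (possibly empty).
#' @export
find_peaks_circular <- function(tc, min_distance_deg = 120,
                                min_width_deg = 40, min_prominence = 11) {
  r <- tc$rate
  r[is.na(r)] <- 0
  n <- length(r)
  left <- r[c(n, 1:(n - 1))]
  right <- r[c(2:n, 1)]
  cand <- which(r > left & r >= right)
  if (!length(cand) || diff(range(r)) == 0) {
    return(data.frame(location_deg = numeric(0), height = numeric(0),
                      prominence = numeric(0), width_deg = numeric(0)))
  }
  prom <- numeric(length(cand))
  width <- numeric(length(cand))
  for (j in seq_along(cand)) {
    p <- cand[j]
    key <- -Inf
    for (dir in c(-1L, 1L)) {
      lo <- r[p]
      i <- p
      for (step in 1:(n - 1)) {
        i <- ((i - 1L + dir) %% n) + 1L
        if (r[i] > r[p]) break
        if (r[i] < lo) lo <- r[i]
        if (step == n - 1L) lo <- min(r)  # global max: key saddle = global min
      }
      if (lo > key) key <- lo
    }
    prom[j] <- r[p] - key
    ref <- r[p] - prom[j] / 2
    cross <- function(dir) {
      i <- p
      for (step in 1:(n - 1)) {
        nxt <- ((i - 1L + dir) %% n) + 1L
        if (r[nxt] < ref) {
          frac <- (r[i] - ref) / (r[i] - r[nxt])
          return(step - 1 + frac)
        }
        i <- nxt
      }
      n / 2  # never crosses: cap at half circle
    }
    width[j] <- (cross(-1L) + cross(1L)) * TC_BINW
  }
  loc <- tc$bin_centers[cand]
  keep <- prom > min_prominence & width >= min_width_deg
  cand <- cand[keep]; loc <- loc[keep]; prom <- prom[keep]; width <- width[keep]
  if (!length(cand)) {
    return(data.frame(location_deg = numeric(0), height = numeric(0),
                      prominence = numeric(0), width_deg = numeric(0)))
  }
  ord <- order(r[cand], decreasing = TRUE)
  sel <- integer(0)
  for (j in ord) {
    d <- abs(wrap_diff(loc[j], loc[sel]))
    if (!length(sel) || all(d >= min_distance_deg)) sel <- c(sel, j)
  }
  sel <- sel[order(r[cand[sel]], decreasing = TRUE)]
  data.frame(location_deg = loc[sel], height = r[cand[sel]],
             prominence = prom[sel], width_deg = width[sel])
}

## --- von Mises fitting -----------------------------------------------------

## von Mises density with numerically safe scaled Bessel
.dvm <- function(delta_rad, kappa) {
  exp(kappa * (cos(delta_rad) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Fit a (multi-peak) von Mises model to a tuning curve
#'
#' Nonlinear least squares of
#' \deqn{\lambda(\theta) = c_1 + \sum_k c_{2,k}
#'  \frac{1}{2\pi I_0(c_{4,k})} e^{c_{4,k}\cos(\theta - c_{3,k})}}
#' to the binned rates, with 1-3 peaks. Starting values come from
#' [find_peaks_circular()] (baseline starts at 0); fitting uses
#' Levenberg-Marquardt with kappa bounded below by 0. A non-converging fit
#' is returned flagged rather than raising.
#'
#' @param tc A `tuning_curve` (raw rates are fit; initialize from the
#'   smoothed curve's peaks).
#' @param peaks Data frame from [find_peaks_circular()]; if `NULL`, peaks
#'   are found on a sigma = 1 bin smoothed copy, falling back to the curve
#'   maximum when no peak passes the constraints.
#' @param n_peaks Number of peaks to fit (1-3); defaults to the number of
#'   detected peaks (capped at 3).
#' @return Object of class `vm_fit`: `coefficients` (baseline `c1` and a
#'   per-peak data frame `scale`, `location_deg`, `kappa`), `fitted`,
#'   `converged`, `kappa_largest` (concentration of the tallest fitted
#'   peak), `rss`.
#' @export
fit_von_mises <- function(tc, peaks = NULL, n_peaks = NULL) {
  if (is.null(peaks)) {
    peaks <- find_peaks_circular(smooth_tuning_curve(tc), min_prominence = 0,
                                 min_width_deg = 0)
  }
  if (!nrow(peaks)) {
    i <- which.max(ifelse(is.na(tc$rate), -Inf, tc$rate))
    peaks <- data.frame(location_deg = tc$bin_centers[i], height = tc$rate[i],
                        prominence = 0, width_deg = 0)
  }
  if (is.null(n_peaks)) n_peaks <- min(nrow(peaks), 3L)
  if (!n_peaks %in% 1:3) stop("n_peaks must be 1, 2 or 3")
  n_peaks <- min(n_peaks, nrow(peaks))
  ok <- tc$occupancy > 0 & !is.na(tc$rate)
  if (sum(ok) < 30) stop("tuning curve defined on fewer than 30 bins")
  th <- deg2rad(tc$bin_centers[ok])
  y <- tc$rate[ok]

  k0 <- 4
  start <- list(c1 = 0)
  lower <- c(0)
  upper <- c(Inf)
  for (k in seq_len(n_peaks)) {
    start[[paste0("a", k)]] <- max(peaks$height[k], 1e-3) * 2 * pi *
      besselI(k0, 0, expon.scaled = TRUE)
    start[[paste0("mu", k)]] <- deg2rad(peaks$location_deg[k])
    start[[paste0("kp", k)]] <- k0
    lower <- c(lower, 0, -Inf, 0)
    upper <- c(upper, Inf, Inf, 500)
  }
  terms <- paste0("a", seq_len(n_peaks), " * .dvm(th - mu", seq_len(n_peaks),
                  ", kp", seq_len(n_peaks), ")", collapse = " + ")
  form <- stats::as.formula(paste("y ~ c1 +", terms))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = list(y = y, th = th), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(coefficients = NULL, fitted = NULL,
                          converged = FALSE, kappa_largest = NA_real_,
                          rss = NA_real_),
                     class = "vm_fit"))
  }
  cf <- stats::coef(fit)
  pk <- data.frame(
    scale = cf[paste0("a", seq_len(n_peaks))],
    location_deg = wrap_deg(rad2deg(cf[paste0("mu", seq_len(n_peaks))])) %% 360,
    kappa = cf[paste0("kp", seq_len(n_peaks))]
  )
  ph <- pk$scale * .dvm(0, pk$kappa)  # fitted peak heights above baseline
  structure(list(coefficients = list(c1 = unname(cf["c1"]), peaks = pk),
                 fitted = stats::fitted(fit),
                 converged = TRUE,
                 kappa_largest = pk$kappa[which.max(ph)],
                 rss = sum(stats::residuals(fit)^2)),
            class = "vm_fit")
}

#' @export
print.vm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<vm_fit> not converged\n")
    return(invisible(x))
  }
  cat("<vm_fit> baseline", sprintf("%.3f", x$coefficients$c1), "Hz;",
      nrow(x$coefficients$peaks), "peak(s)\n")
  print(x$coefficients$peaks, digits = 4)
  invisible(x)
}

## --- shuffle null & classification ----------------------------------------

## per-unit HD metrics of one segment: info and resultant from the raw
## curve, concentration from the smoothed curve (von Mises fit for
## multi-peak units)
.segment_metrics <- function(spike_times, tracking, mask, sigma_bins = 1) {
  tc <- compute_tuning_curve(spike_times, tracking, mask)
  stc <- smooth_tuning_curve(tc, sigma_bins)
  pk <- find_peaks_circular(stc)
  n_peaks <- max(1L, nrow(pk))
  kap <- if (nrow(pk) > 1) {
    vf <- fit_von_mises(tc, peaks = pk, n_peaks = min(nrow(pk), 3L))
    if (vf$converged) vf$kappa_largest else NA_real_
  } else tc_concentration(stc)
  rp <- resultant_and_pfd(stc)
  list(info = directional_information(tc), R = resultant_and_pfd(tc)$R,
       kappa = kap, pfd_deg = rp$pfd_deg, n_peaks = n_peaks, tc = tc)
}

#' Shuffle null for HD-metric thresholds
#'
#' Circularly time-shifts the spike train within the analysis segment
#' (uniform shifts at least `min_shift_s` from either end), recomputes
#' information, resultant and concentration for each shuffle, and returns
#' the 98th percentile of each metric.
#'
#' @param spike_times Spike times (s).
#' @param tracking 50 Hz tracking data frame.
#' @param mask Analysis segment (see [compute_tuning_curve()]); must span
#'   at least 60 s.
#' @param n Number of shuffles.
#' @param min_shift_s Minimum circular shift (s).
#' @param probs Threshold percentile.
#' @param sigma_bins Smoothing SD for the concentration metric.
#' @return List `thresholds` (named: info, R, kappa) and `distributions`
#'   (n x 3 matrix).
#' @export
shuffle_null <- function(spike_times, tracking, mask = NULL, n = 500,
                         min_shift_s = 20, probs = 0.98, sigma_bins = 1) {
  keep <- .tracking_mask(tracking, mask)
  dt <- tracking$time_s[2] - tracking$time_s[1]
  m <- sum(keep)
  if (m * dt < 60) stop("segment shorter than 60 s")
  bins <- .hd_bins(tracking$hd_deg)[keep]
  occ <- tabulate(bins, TC_NBINS) * dt

  si <- .spike_samples(spike_times, tracking)
  si <- si[!is.na(si)]
  si <- si[keep[si]]
  pos <- match(si, which(keep))
  pos <- pos[!is.na(pos)]
  if (!length(pos)) stop("no spikes in segment")

  shifts <- round(stats::runif(n, min_shift_s, m * dt - min_shift_s) / dt)
  idx <- outer(pos, shifts, "+")
  idx <- ((idx - 1L) %% m) + 1L
  binm <- matrix(bins[idx], nrow = length(pos))
  offs <- rep(seq.int(0L, by = TC_NBINS, length.out = n), each = length(pos))
  cnt <- matrix(tabulate(as.vector(binm) + offs, TC_NBINS * n), nrow = TC_NBINS)

  ## raw-curve metrics, vectorized over shuffles
  p <- occ / sum(occ)
  rate <- sweep(cnt, 1, occ, "/")
  rate[occ == 0, ] <- 0
  lbar <- colSums(rate * p)
  rel <- sweep(rate, 2, lbar, "/")
  info <- colSums(ifelse(rel > 0, rel * log2(rel), 0) * p)
  z <- exp(1i * deg2rad(seq(TC_BINW / 2, 360 - TC_BINW / 2, by = TC_BINW)))
  R <- Mod(colSums(rate * z) / colSums(rate))
  ## smoothed-curve concentration
  scnt <- Re(stats::mvfft(stats::mvfft(cnt) *
                          .smooth_kernel_f(TC_NBINS, sigma_bins), inverse = TRUE)) / TC_NBINS
  socc <- .circ_gauss_smooth(occ, sigma_bins)
  srate <- sweep(pmax(scnt, 0), 1, pmax(socc, 1e-12), "/")
  Rs <- Mod(colSums(srate * z) / colSums(srate))
  kap <- kappa_from_R(Rs)

  dist <- cbind(info = info, R = R, kappa = kap)
  list(thresholds = apply(dist, 2, stats::quantile, probs = probs, names = FALSE),
       distributions = dist)
}

.smooth_kernel_f <- function(n, sigma_bins) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  exp(-0.5 * (k * sigma_bins * 2 * pi / n)^2)
}

#' Classify a unit as head-direction coding
#'
#' A unit is HD if directional information, resultant length and
#' concentration all exceed the 98th percentile of their spike-shift
#' shuffle distributions on BOTH of two distinct stable cue-on segments.
#' Concentration comes from the smoothed curve for single-peak units and
#' from the largest peak of the von Mises fit for multi-peak units. Units
#' with no spikes or insufficient heading coverage are `"unclassifiable"`
#' (a third label, distinct from non-HD).
#'
#' @param spike_times Spike times (s).
#' @param tracking 50 Hz tracking data frame.
#' @param segment1,segment2 Interval matrices (or logical masks) of the two
#'   qualifying segments.
#' @param n_shuffle Shuffles per segment.
#' @param min_occ_bins Minimum number of bins with at least
#'   `min_occ_s` occupancy for the segment to count as substantial
#'   coverage.
#' @param min_occ_s See `min_occ_bins`.
#' @param sigma_bins Tuning-curve smoothing SD (bins).
#' @return Object of class `hd_metrics`: per-segment metrics and
#'   thresholds, `label` (`"HD"`, `"non-HD"`, `"unclassifiable"`) and
#'   `is_hd`.
#' @export
classify_hd_unit <- function(spike_times, tracking, segment1, segment2,
                             n_shuffle = 500, min_occ_bins = 33,
                             min_occ_s = 1, sigma_bins = 1) {
  segs <- list(segment1, segment2)
  per_seg <- vector("list", 2)
  for (s in 1:2) {
    tc <- compute_tuning_curve(spike_times, tracking, segs[[s]])
    if (tc$n_spikes == 0 || sum(tc$occupancy >= min_occ_s) < min_occ_bins) {
      return(structure(list(label = "unclassifiable", is_hd = FALSE,
                            segments = NULL),
                       class = "hd_metrics"))
    }
    met <- .segment_metrics(spike_times, tracking, segs[[s]], sigma_bins)
    nul <- shuffle_null(spike_times, tracking, segs[[s]], n = n_shuffle,
                        sigma_bins = sigma_bins)
    per_seg[[s]] <- list(metrics = met, thresholds = nul$thresholds)
  }
  pass <- vapply(per_seg, function(x) {
    m <- x$metrics; th <- x$thresholds
    !is.na(m$kappa) && m$info > th["info"] && m$R > th["R"] && m$kappa > th["kappa"]
  }, logical(1))
  structure(list(label = if (all(pass)) "HD" else "non-HD",
                 is_hd = all(pass),
                 segments = per_seg),
            class = "hd_metrics")
}

#' @export
print.hd_metrics <- function(x, ...) {
  cat("<hd_metrics>", x$label, "\n")
  if (!is.null(x$segments)) {
    for (s in 1:2) {
      m <- x$segments[[s]]$metrics
      th <- x$segments[[s]]$thresholds
      cat(sprintf("  seg%d: info %.3f (thr %.3f)  R %.3f (thr %.3f)  kappa %.2f (thr %.2f)  PFD %.0f\n",
                  s, m$info, th["info"], m$R, th["R"], m$kappa, th["kappa"], m$pfd_deg))
    }
  }
  invisible(x)
}

#' Angular velocity from tracked heading
#'
#' First derivative of the unwrapped heading, computed on a 500 ms
#' decimated series and linearly re-interpolated back to the 50 Hz grid.
#'
#' @param tracking 50 Hz tracking data frame.
#' @return Angular velocity (deg/s) at the tracking timestamps.
#' @export
angular_velocity <- function(tracking) {
  t <- tracking$time_s
  u <- unwrap_deg(tracking$hd_deg)
  ds <- seq(1L, length(t), by = 25L)  # 500 ms decimation
  if (length(ds) < 2L) return(rep(0, length(t)))
  av_ds <- diff(u[ds]) / diff(t[ds])
  t_mid <- (t[ds[-1]] + t[ds[-length(ds)]]) / 2
  stats::approx(t_mid, av_ds, xout = t, rule = 2)$y
}
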