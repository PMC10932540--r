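## Population decoding of heading: a linear-Gaussian model mapping 20 ms
## binned, low-pass-filtered, z-scored population rates to the sine and
## cosine of heading via ridge regression. Decoded heading is the atan2 of
## the two predictions; the decoded error is the wrapped difference between
## tracked and decoded heading, whose offset tracks the internal HD
## reference frame.

DEC_BIN <- 0.02

#' Bin spike trains into a 20 ms rate matrix
#'
#' @param spikes Named list of spike-time vectors.
#' @param t_range Numeric `c(start, end)` in seconds.
#' @param bin Bin width (s).
#' @return Matrix (bins x units) of rates in Hz, with attribute `time_s`
#'   (bin centers).
#' @export
bin_rates <- function(spikes, t_range, bin = DEC_BIN) {
  nb <- floor((t_range[2] - t_range[1]) / bin + 1e-9)
  if (nb < 1) stop("empty time range")
  m <- vapply(spikes, function(ts) {
    ts <- ts[ts >= t_range[1] & ts < t_range[1] + nb * bin]
    tabulate(floor((ts - t_range[1]) / bin) + 1L, nb) / bin
  }, numeric(nb))
  if (is.null(dim(m))) m <- matrix(m, nrow = nb)
  attr(m, "time_s") <- t_range[1] + (seq_len(nb) - 0.5) * bin
  m
}

#' Low-pass filter rate columns (zero-phase Butterworth)
#'
#' Order-3 Butterworth with normalized cutoff 0.2, applied forward and
#' backward (`filtfilt`) so that filtering adds no lag -- essential for the
#' downstream inter-regional lag analysis.
#'
#' @param rates Bins x units rate matrix.
#' @param cutoff Normalized cutoff frequency (1 = Nyquist).
#' @param order Filter order.
#' @return Filtered matrix (attributes preserved).
#' @useDynLib hdsync, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @export
filter_rates <- function(rates, cutoff = 0.2, order = 3) {
  bf <- signal::butter(order, cutoff)
  out <- .filtfilt_mat(bf$b, bf$a, as.matrix(rates))
  dimnames(out) <- dimnames(rates)
  attr(out, "time_s") <- attr(rates, "time_s")
  out
}

## heading interpolated (on the unwrapped trace) to arbitrary times
.heading_at <- function(tracking, times) {
  u <- unwrap_deg(tracking$hd_deg)
  stats::approx(tracking$time_s, u, xout = times, rule = 2)$y %% 360
}

#' Fit the heading decoder (ridge regression on sine and cosine)
#'
#' Builds 20 ms population rates for one region over the whole session,
#' low-pass filters them, z-scores each unit using training-window
#' statistics only, and fits two ridge regressions (shared penalty) from
#' the z-scored rates to the sine and cosine of heading, with the target
#' angle quantized to 10-degree bin centers. Decoding inverts via atan2.
#'
#' @param session An `hd_session` (or list with `spikes`, `units`,
#'   `tracking`).
#' @param region `"A"` or `"B"`.
#' @param train_window `c(start, end)` seconds; must span at least 120 s.
#' @param lambda Ridge penalty on the z-scored predictors.
#' @param cutoff,order Butterworth filter parameters.
#' @param units Optional character vector restricting the ensemble.
#' @return Object of class `hd_decoder` with elements `weights` (units x
#'   2, sin and cos), `intercepts`, `mu`/`sd` (training normalization),
#'   `lambda`, `filter`, `units`, `train_window`, `coverage_warning`, and
#'   the processed predictor matrix for fast prediction.
#' @export
hd_decoder <- function(session, region = "A", train_window, lambda = 1,
                       cutoff = 0.2, order = 3, units = NULL) {
  if (is.null(units)) units <- session$units$unit_id[session$units$region == region]
  if (!length(units)) stop("no units in region ", region)
  if (diff(train_window) < 120) stop("training window must span at least 120 s")
  tr <- session$tracking
  t_range <- c(tr$time_s[1], tr$time_s[nrow(tr)] + DEC_BIN)
  raw <- bin_rates(session$spikes[units], t_range)
  filt <- filter_rates(raw, cutoff, order)
  times <- attr(raw, "time_s")
  tr_idx <- times >= train_window[1] & times < train_window[2]

  mu <- colMeans(filt[tr_idx, , drop = FALSE])
  sd <- apply(filt[tr_idx, , drop = FALSE], 2, stats::sd)
  keep <- sd > 1e-10
  if (!all(keep)) {
    warning(sum(!keep), " unit(s) with zero training-window variance excluded")
    units <- units[keep]
    filt <- filt[, keep, drop = FALSE]
    mu <- mu[keep]; sd <- sd[keep]
    if (!length(units)) stop("no usable units")
  }
  X <- sweep(sweep(filt, 2, mu), 2, sd, "/")

  hd <- .heading_at(tr, times)
  q <- (floor(hd / 10) %% 36) * 10 + 5  # 10-degree target quantization
  ys <- sin(deg2rad(q)); yc <- cos(deg2rad(q))

  cov_bins <- length(unique(floor(hd[tr_idx] / 10)))
  coverage_warning <- cov_bins * 10 < 180
  if (coverage_warning)
    warning("training heading coverage below 180 degrees")

  Xt <- X[tr_idx, , drop = FALSE]
  A <- crossprod(Xt) + diag(lambda, ncol(Xt))
  is_ <- mean(ys[tr_idx]); ic_ <- mean(yc[tr_idx])
  W <- solve(A, crossprod(Xt, cbind(ys[tr_idx] - is_, yc[tr_idx] - ic_)))
  colnames(W) <- c("sin", "cos")
  rownames(W) <- units

  structure(list(weights = W, intercepts = c(sin = is_, cos = ic_),
                 mu = mu, sd = sd, lambda = lambda,
                 filter = list(cutoff = cutoff, order = order),
                 units = units, region = region,
                 train_window = train_window,
                 coverage_warning = coverage_warning,
                 X = X, time_s = times, tracked_deg = .heading_at(tr, times)),
            class = "hd_decoder")
}

#' @export
print.hd_decoder <- function(x, ...) {
  cat("<hd_decoder> region", x$region, "-", length(x$units), "units, ridge lambda",
      x$lambda, "\n  trained on", sprintf("[%.0f, %.0f] s", x$train_window[1],
                                          x$train_window[2]),
      if (x$coverage_warning) " (low heading coverage)" else "", "\n")
  invisible(x)
}

#' @export
coef.hd_decoder <- function(object, ...) {
  rbind(`(Intercept)` = object$intercepts, object$weights)
}

#' Decode heading from a fitted decoder
#'
#' Predicts sine and cosine from the processed population rates, inverts
#' via atan2, and returns the decoded trajectory together with the decoded
#' error, the wrapped difference between tracked and decoded heading
#' (positive when the internal reference has rotated positively).
#'
#' @param object An `hd_decoder`.
#' @param window Optional `c(start, end)` restricting the output (s).
#' @param newdata Optional replacement processed predictor matrix
#'   (bins x units), e.g. for shuffle controls.
#' @param ... Unused.
#' @return Data frame of class `decoded_trajectory`: `time_s`,
#'   `decoded_deg`, `tracked_deg`, `error_deg` in (-180, 180].
#' @export
predict.hd_decoder <- function(object, window = NULL, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else newdata
  s <- X %*% object$weights[, "sin"] + object$intercepts["sin"]
  cc <- X %*% object$weights[, "cos"] + object$intercepts["cos"]
  dec <- rad2deg(atan2(s, cc)) %% 360
  dec[s == 0 & cc == 0] <- NA_real_
  out <- data.frame(time_s = object$time_s,
                    decoded_deg = as.numeric(dec),
                    tracked_deg = object$tracked_deg)
  out$error_deg <- ifelse(is.na(out$decoded_deg), NA_real_,
                          wrap_diff(out$tracked_deg, out$decoded_deg))
  if (!is.null(window))
    out <- out[out$time_s >= window[1] & out$time_s < window[2], , drop = FALSE]
  class(out) <- c("decoded_trajectory", "data.frame")
  out
}

#' Decoding accuracy: median absolute decoded error
#'
#' @param traj A `decoded_trajectory`.
#' @param window Optional `c(start, end)` (s).
#' @return Median of `|error_deg|` (degrees), NA bins excluded.
#' @export
decoding_accuracy <- function(traj, window = NULL) {
  e <- traj$error_deg
  if (!is.null(window))
    e <- e[traj$time_s >= window[1] & traj$time_s < window[2]]
  stats::median(abs(e), na.rm = TRUE)
}

#' Shuffle gate for decoded sessions
#'
#' Re-decodes the session `n` times after circularly shifting each unit's
#' spike train by an independent random amount (implemented as a circular
#' shift of its 20 ms count series), retraining the decoder each time. The
#' session is included if the real test accuracy is below the 10th
#' percentile of the shuffle accuracies.
#'
#' @param session An `hd_session`.
#' @param region `"A"` or `"B"`.
#' @param train_window,test_window Training and evaluation windows (s).
#' @param n Number of shuffles.
#' @param min_shift_s Minimum circular shift (s).
#' @param lambda,cutoff,order Decoder parameters.
#' @param units Optional ensemble restriction.
#' @return List: `include`, `real_accuracy`, `shuffle_accuracy` (length
#'   n), `threshold` (10th percentile).
#' @export
shuffle_gate <- function(session, region = "A", train_window, test_window,
                         n = 100, min_shift_s = 20, lambda = 1,
                         cutoff = 0.2, order = 3, units = NULL) {
  model <- hd_decoder(session, region, train_window, lambda, cutoff, order, units)
  real <- decoding_accuracy(predict(model), test_window)

  tr <- session$tracking
  t_range <- c(tr$time_s[1], tr$time_s[nrow(tr)] + DEC_BIN)
  raw <- bin_rates(session$spikes[model$units], t_range)
  times <- attr(raw, "time_s")
  nb <- nrow(raw)
  tr_idx <- times >= train_window[1] & times < train_window[2]
  hd <- .heading_at(tr, times)
  q <- (floor(hd / 10) %% 36) * 10 + 5
  ys <- sin(deg2rad(q)); yc <- cos(deg2rad(q))
  te_idx <- times >= test_window[1] & times < test_window[2]
  tracked_te <- hd[te_idx]
  min_b <- max(1L, round(min_shift_s / DEC_BIN))

  acc <- numeric(n)
  for (i in seq_len(n)) {
    sh <- sample((min_b):(nb - min_b), ncol(raw), replace = TRUE)
    Xs <- raw
    for (j in seq_len(ncol(raw))) {
      k <- sh[j]
      Xs[, j] <- raw[c((nb - k + 1):nb, 1:(nb - k)), j]
    }
    Xs <- filter_rates(Xs, cutoff, order)
    Xtr <- Xs[tr_idx, , drop = FALSE]
    ntr <- nrow(Xtr)
    mu <- colMeans(Xtr)
    sd <- sqrt(pmax(colSums(Xtr^2) - ntr * mu^2, 0) / (ntr - 1))
    ok <- sd > 1e-10
    nbr <- nrow(Xs)
    Z <- (Xs[, ok, drop = FALSE] - rep(mu[ok], each = nbr)) *
      rep(1 / sd[ok], each = nbr)
    Zt <- Z[tr_idx, , drop = FALSE]
    A <- crossprod(Zt) + diag(lambda, ncol(Zt))
    W <- solve(A, crossprod(Zt, cbind(ys[tr_idx] - mean(ys[tr_idx]),
                                      yc[tr_idx] - mean(yc[tr_idx]))))
    Zte <- Z[te_idx, , drop = FALSE]
    sv <- Zte %*% W[, 1] + mean(ys[tr_idx])
    cv <- Zte %*% W[, 2] + mean(yc[tr_idx])
    dec <- rad2deg(atan2(sv, cv)) %% 360
    acc[i] <- stats::median(abs(wrap_diff(tracked_te, dec)))
  }
  thr <- stats::quantile(acc, 0.10, names = FALSE)
  list(include = real < thr, real_accuracy = real,
       shuffle_accuracy = acc, threshold = thr, model = model)
}

#' Decoded ensemble rotation between two windows
#'
#' Circular mean of the decoded error in the post window minus that in the
#' pre window, wrapped: the rotation of the internal HD reference as seen
#' by the decoder.
#'
#' @param traj A `decoded_trajectory`.
#' @param pre_window,post_window `c(start, end)` seconds; each must span
#'   at least 60 s.
#' @return Rotation in degrees, in (-180, 180].
#' @export
decoded_rotation <- function(traj, pre_window, post_window) {
  if (diff(pre_window) < 60 || diff(post_window) < 60)
    stop("rotation windows must span at least 60 s")
  get_mean <- function(w) {
    e <- traj$error_deg[traj$time_s >= w[1] & traj$time_s < w[2]]
    if (mean(is.na(e)) > 0.5) stop("window dominated by undefined decoded error")
    circ_mean_resultant(e[!is.na(e)])$mean_deg
  }
  wrap_diff(get_mean(post_window), get_mean(pre_window))
}

#' @export
plot.decoded_trajectory <- function(x, ...) {
  graphics::plot(x$time_s, x$tracked_deg, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "heading (deg)", ylim = c(0, 360), ...)
  graphics::points(x$time_s, x$decoded_deg, pch = ".", col = "firebrick")
  invisible(x)
}
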