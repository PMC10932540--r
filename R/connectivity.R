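## Putative excitatory monosynaptic connection detection from pairwise
## spike cross-correlograms (CCGs): 0.5 ms bins over +/- 50 ms, a
## Gaussian-convolved baseline (10 ms SD) standing in for homogeneous
## firing, and a cumulative-Poisson 99.9% per-bin test requiring at least
## two consecutive significant bins in the 1-5 ms lag window.

CCG_BIN <- 5e-4
CCG_WIN <- 0.05

.mask_times <- function(ts, mask) {
  if (is.null(mask)) return(ts)
  iv <- matrix(as.numeric(as.matrix(mask)), ncol = 2)
  keep <- rep(FALSE, length(ts))
  for (k in seq_len(nrow(iv)))
    keep <- keep | (ts >= iv[k, 1] & ts < iv[k, 2])
  ts[keep]
}

#' Spike-pair cross-correlogram
#'
#' Histogram of all spike-time lags `t_post - t_pre` within +/- 50 ms, in
#' 0.5 ms bins (exact integer counts; both trains may be restricted to a
#' set of time intervals, e.g. cue-on trials).
#'
#' @param pre,post Spike-time vectors (s), sorted.
#' @param mask Optional two-column interval matrix (s).
#' @param window Half-width of the correlogram (s).
#' @param bin Bin width (s).
#' @return Object of class `ccg`: `lag_s` (bin centers), `counts`,
#'   `n_pre`, `n_post`.
#' @export
compute_ccg <- function(pre, post, mask = NULL, window = CCG_WIN, bin = CCG_BIN) {
  pre <- .mask_times(pre, mask)
  post <- .mask_times(post, mask)
  if (!length(pre) || !length(post)) stop("empty spike train in CCG")
  lo <- findInterval(pre - window * 1.01, post) + 1L
  hi <- findInterval(pre + window * 1.01, post)
  nper <- pmax(hi - lo + 1L, 0L)
  keep <- nper > 0L
  d <- post[sequence(nper[keep], from = lo[keep])] - rep(pre[keep], nper[keep])
  ## lags rounded to a 10 us grid (immaterial against 0.5 ms bins) so that
  ## diffs sitting on a bin or window edge -- spikes live on a 0.1 ms
  ## sub-grid -- bin identically under float round-off: the CCG is then
  ## exactly invariant under joint time translation of both trains
  d <- round(d / 1e-5) * 1e-5
  d <- d[abs(d) <= window]
  nb <- round(2 * window / bin)
  edges <- seq(-window, window, by = bin)
  idx <- floor((d + window) / bin + 1e-6) + 1L
  idx[idx > nb] <- nb  # d == +window lands in the last bin
  counts <- tabulate(idx, nb)
  structure(list(lag_s = edges[-1] - bin / 2, counts = counts,
                 n_pre = length(pre), n_post = length(post)),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat("<ccg>", length(x$counts), "bins of", (x$lag_s[2] - x$lag_s[1]) * 1000,
      "ms;", sum(x$counts), "spike pairs\n")
  invisible(x)
}

#' @export
plot.ccg <- function(x, baseline = NULL, ...) {
  graphics::plot(x$lag_s * 1000, x$counts, type = "h",
                 xlab = "lag (ms)", ylab = "count", ...)
  if (!is.null(baseline))
    graphics::lines(x$lag_s * 1000, baseline, col = "red", lwd = 2)
  invisible(x)
}

#' Convolved CCG baseline
#'
#' Expected counts under homogeneous firing: the correlogram convolved
#' with a Gaussian window (default SD 10 ms = 20 bins). Reflection padding
#' at the edges keeps a flat correlogram exactly flat and conserves the
#' total count mass. Set `hollow = TRUE` to exclude each bin's own count
#' from its baseline (partial-hollow variant).
#'
#' @param ccg A [compute_ccg()] result.
#' @param sigma_ms Kernel SD (ms).
#' @param hollow Exclude the kernel center?
#' @return Baseline counts per bin.
#' @export
ccg_baseline <- function(ccg, sigma_ms = 10, hollow = FALSE) {
  bin_ms <- (ccg$lag_s[2] - ccg$lag_s[1]) * 1000
  sb <- sigma_ms / bin_ms
  half <- ceiling(5 * sb)
  k <- stats::dnorm(-half:half, sd = sb)
  if (hollow) k[half + 1] <- 0
  k <- k / sum(k)
  x <- ccg$counts
  n <- length(x)
  half <- min(half, n - 1L)
  k <- k[(length(k) + 1) / 2 + (-half:half)]
  k <- k / sum(k)
  xp <- c(x[half:1], x, x[n:(n - half + 1)])
  full <- stats::convolve(xp, rev(k), type = "open")
  full[(2 * half + 1):(2 * half + n)]
}

#' Detect a putative excitatory monosynaptic connection
#'
#' Tests the 0.5 ms bins with lags in (1, 5] ms (or [-5, -1) ms for
#' `direction = "neg"`): a bin is significant when its count exceeds the
#' 99.9th percentile of the cumulative Poisson distribution at its
#' baseline rate, i.e. `count > qpois(0.999, baseline)`. A connection
#' requires at least two consecutive significant bins; its latency is the
#' lag of the highest-count bin among the qualifying ones.
#'
#' @param ccg A `ccg`.
#' @param baseline Baseline from [ccg_baseline()] (computed if `NULL`).
#' @param direction `"pos"` (pre leads post) or `"neg"`.
#' @param lag_range_ms Tested latency window (ms).
#' @param level Per-bin cumulative-Poisson level.
#' @return `NULL`, or a list `latency_ms`, `excess` (count minus baseline
#'   at the peak bin), `n_sig_bins`, `direction`.
#' @export
detect_connection <- function(ccg, baseline = NULL, direction = c("pos", "neg"),
                              lag_range_ms = c(1, 5), level = 0.999) {
  direction <- match.arg(direction)
  if (is.null(baseline)) baseline <- ccg_baseline(ccg)
  lag_ms <- ccg$lag_s * 1000
  sel <- if (direction == "pos") {
    lag_ms > lag_range_ms[1] & lag_ms <= lag_range_ms[2]
  } else {
    lag_ms < -lag_range_ms[1] & lag_ms >= -lag_range_ms[2]
  }
  idx <- which(sel)
  thr <- stats::qpois(level, baseline[idx])
  sig <- ccg$counts[idx] > thr
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  runs <- which(r$values & r$lengths >= 2)
  if (!length(runs)) return(NULL)
  qual <- unlist(lapply(runs, function(k) (ends[k] - r$lengths[k] + 1):ends[k]))
  peak <- idx[qual][which.max(ccg$counts[idx][qual])]
  list(latency_ms = lag_ms[peak],
       excess = ccg$counts[peak] - baseline[peak],
       n_sig_bins = sum(sig), direction = direction)
}

#' Census of putative connections across two regions
#'
#' Computes CCGs for all region-A x region-B pairs, detects connections in
#' both directions (A to B at positive lags, B to A at negative lags), and
#' summarizes them against HD classification and waveform class: counts by
#' direction and class, and the circular statistics (mean, SD, Rayleigh
#' test) of the PFD differences of connected HD-HD pairs, with matched
#' statistics for the non-connected HD partners of the same presynaptic
#' units.
#'
#' @param session An `hd_session`.
#' @param hd_table Data frame with columns `unit_id`, `is_hd`, `pfd_deg`
#'   (PFD may be NA for non-HD units).
#' @param wf_class Optional named character vector (`"RS"`/`"FS"`) per
#'   unit.
#' @param mask Optional interval matrix restricting spikes (cue state).
#' @param ... Passed to [detect_connection()].
#' @return Object of class `connection_census`: `connections` data frame,
#'   `counts` table, `pfd_stats` (connected and matched non-connected
#'   pairs).
#' @export
connection_census <- function(session, hd_table, wf_class = NULL, mask = NULL, ...) {
  ua <- session$units$unit_id[session$units$region == "A"]
  ub <- session$units$unit_id[session$units$region == "B"]
  rows <- list()
  for (a in ua) {
    for (b in ub) {
      ccg <- tryCatch(compute_ccg(session$spikes[[a]], session$spikes[[b]], mask),
                      error = function(e) NULL)
      if (is.null(ccg)) next
      base <- ccg_baseline(ccg)
      for (dir in c("pos", "neg")) {
        det <- detect_connection(ccg, base, dir, ...)
        if (!is.null(det)) {
          rows[[length(rows) + 1L]] <- data.frame(
            pre = if (dir == "pos") a else b,
            post = if (dir == "pos") b else a,
            direction = if (dir == "pos") "A->B" else "B->A",
            latency_ms = abs(det$latency_ms), excess = det$excess)
        }
      }
    }
  }
  connections <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pre = character(0), post = character(0),
               direction = character(0), latency_ms = numeric(0),
               excess = numeric(0))

  hd <- stats::setNames(hd_table$is_hd, hd_table$unit_id)
  pfd <- stats::setNames(hd_table$pfd_deg, hd_table$unit_id)
  counts <- NULL
  if (nrow(connections)) {
    connections$pre_hd <- unname(hd[connections$pre])
    connections$post_hd <- unname(hd[connections$post])
    if (!is.null(wf_class)) connections$post_class <- unname(wf_class[connections$post])
    counts <- table(direction = connections$direction,
                    pre_hd = connections$pre_hd, post_hd = connections$post_hd)
  }

  pfd_stats <- function(pairs) {
    if (is.null(pairs) || !nrow(pairs)) return(NULL)
    d <- wrap_diff(pfd[pairs$post], pfd[pairs$pre])
    d <- d[!is.na(d)]
    if (length(d) < 5) return(list(n = length(d), diffs_deg = d))
    m <- circ_mean_resultant(d)
    list(n = length(d), diffs_deg = d, mean_deg = m$mean_deg,
         sd_deg = circ_sd_deg(m$R), rayleigh_p = rayleigh_test(d)$p.value)
  }
  ab <- connections[connections$direction == "A->B" &
                      !is.na(connections$pre_hd) & connections$pre_hd &
                      !is.na(connections$post_hd) & connections$post_hd, , drop = FALSE]
  ## matched: same presynaptic HD units against their non-connected HD partners
  nonpairs <- NULL
  if (nrow(ab)) {
    hd_b <- ub[!is.na(hd[ub]) & hd[ub]]
    np <- expand.grid(pre = unique(ab$pre), post = hd_b,
                      stringsAsFactors = FALSE)
    con_key <- paste(ab$pre, ab$post)
    np <- np[!paste(np$pre, np$post) %in% con_key, , drop = FALSE]
    nonpairs <- np
  }
  structure(list(connections = connections, counts = counts,
                 pfd_stats = list(connected = pfd_stats(ab),
                                  non_connected = pfd_stats(nonpairs))),
            class = "connection_census")
}

#' @export
print.connection_census <- function(x, ...) {
  cat("<connection_census>", nrow(x$connections), "putative connections\n")
  if (nrow(x$connections)) print(table(x$connections$direction))
  st <- x$pfd_stats$connected
  if (!is.null(st) && !is.null(st$mean_deg))
    cat(sprintf("  connected HD-HD pairs: n=%d, circ mean dPFD %.1f deg, Rayleigh p=%.3g\n",
                st$n, st$mean_deg, st$rayleigh_p))
  invisible(x)
}
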