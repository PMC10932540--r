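## RS/FS classification from mean spike waveforms. The peak-to-trough
## duration is the time between the spike's dominant deflection and the
## maximum of the afterhyperpolarization; units above 0.42 ms are
## regular-spiking (putative pyramidal), at or below fast-spiking
## (putative interneuron).

RS_FS_CUTOFF_MS <- 0.42

#' Waveform features for cell-type classification
#'
#' Interpolates the mean waveform to a 0.01 ms grid, normalizes polarity
#' so the spike's dominant deflection is negative, and measures (i) the
#' peak-to-trough duration: time from the spike trough to the maximum of
#' the afterhyperpolarization, and (ii) the symmetry index: the difference
#' between the maxima after and before the spike trough divided by their
#' sum.
#'
#' @param waveform Numeric mean waveform.
#' @param sample_rate Samples per second (>= 20 kHz).
#' @return List `peak_to_trough_ms`, `symmetry`, `class` (`"RS"`/`"FS"`).
#' @export
waveform_features <- function(waveform, sample_rate) {
  if (sample_rate < 20000) stop("sample rate must be at least 20 kHz")
  if (diff(range(waveform)) < .Machine$double.eps^0.5 * max(1, max(abs(waveform))))
    stop("flat waveform")
  t_ms <- (seq_along(waveform) - 1) / sample_rate * 1000
  grid <- seq(0, max(t_ms), by = 0.01)
  w <- stats::spline(t_ms, waveform, xout = grid)$y
  if (max(w) > -min(w)) w <- -w  # dominant deflection negative
  i_tr <- which.min(w)
  if (i_tr >= length(w) - 2) stop("spike trough at waveform edge")
  post <- w[(i_tr + 1):length(w)]
  i_ahp <- i_tr + which.max(post)
  ptt <- grid[i_ahp] - grid[i_tr]
  pre_max <- if (i_tr > 1) max(w[1:(i_tr - 1)]) else 0
  post_max <- max(post)
  sym <- if (post_max + pre_max != 0) (post_max - pre_max) / (post_max + pre_max) else 0
  list(peak_to_trough_ms = ptt, symmetry = sym,
       class = classify_waveform(ptt))
}

#' Classify a unit as regular- or fast-spiking
#'
#' @param peak_to_trough_ms Peak-to-trough duration in ms (or a feature
#'   list from [waveform_features()]).
#' @param cutoff_ms Classification cutoff; RS strictly above, FS at or
#'   below.
#' @return `"RS"` or `"FS"`.
#' @export
classify_waveform <- function(peak_to_trough_ms, cutoff_ms = RS_FS_CUTOFF_MS) {
  if (is.list(peak_to_trough_ms)) peak_to_trough_ms <- peak_to_trough_ms$peak_to_trough_ms
  if (!is.finite(peak_to_trough_ms) || peak_to_trough_ms <= 0)
    stop("invalid peak-to-trough duration")
  if (peak_to_trough_ms > cutoff_ms) "RS" else "FS"
}

#' Classify all units of a session from their mean waveforms
#'
#' @param session An `hd_session` (with `waveforms` and `wf_sample_rate`).
#' @return Data frame `unit_id`, `peak_to_trough_ms`, `symmetry`, `class`.
#' @export
classify_session_waveforms <- function(session) {
  feats <- lapply(seq_len(nrow(session$waveforms)), function(i)
    waveform_features(session$waveforms[i, ], session$wf_sample_rate))
  data.frame(unit_id = session$units$unit_id,
             peak_to_trough_ms = vapply(feats, `[[`, numeric(1), "peak_to_trough_ms"),
             symmetry = vapply(feats, `[[`, numeric(1), "symmetry"),
             class = vapply(feats, `[[`, character(1), "class"))
}
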