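## Session bundle I/O and the pipeline driver. The interchange format is
## tab-separated columnar text: spikes.tsv (unit_id, region, time_s),
## tracking.tsv (time_s, hd_deg), events.tsv (time_s, event, value),
## waveforms.tsv (unit_id + one column per sample), plus truth.yaml /
## truth_series.tsv for synthetic ground truth.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a session bundle to a directory
#'
#' @param session An `hd_session`.
#' @param dir Output directory (created if needed).
#' @param truth Also write the ground truth (`truth.yaml`,
#'   `truth_series.tsv` at 50 Hz)?
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- stats::setNames(session$units$region, session$units$unit_id)
  spk <- data.frame(
    unit_id = rep(names(session$spikes), lengths(session$spikes)),
    region = rep(unname(reg[names(session$spikes)]), lengths(session$spikes)),
    time_s = .fmt(unlist(session$spikes, use.names = FALSE)))
  utils::write.table(spk, file.path(dir, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  trk <- data.frame(time_s = .fmt(session$tracking$time_s),
                    hd_deg = .fmt(session$tracking$hd_deg))
  utils::write.table(trk, file.path(dir, "tracking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(session$events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(session$waveforms)) {
    wf <- data.frame(unit_id = session$units$unit_id,
                     sample_rate = session$wf_sample_rate,
                     session$waveforms)
    utils::write.table(wf, file.path(dir, "waveforms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (truth && !is.null(session$truth)) {
    tu <- session$truth
    yaml::write_yaml(list(
      seed = session$seed,
      units = lapply(seq_len(nrow(tu$units)), function(i) as.list(tu$units[i, ])),
      connections = if (nrow(tu$connections)) {
        lapply(seq_len(nrow(tu$connections)), function(i) as.list(tu$connections[i, ]))
      } else list(),
      wf_class = as.list(stats::setNames(tu$wf_class, session$units$unit_id))
    ), file.path(dir, "truth.yaml"))
    idx <- seq(1L, length(tu$heading_deg), by = 20L)
    ts <- data.frame(time_s = .fmt((idx - 1L) * 1e-3),
                     heading_deg = .fmt(tu$heading_deg[idx]),
                     offset_A = .fmt(tu$offset[idx, "A"]),
                     offset_B = .fmt(tu$offset[idx, "B"]),
                     cue_on = as.integer(tu$cue_on[idx]))
    utils::write.table(ts, file.path(dir, "truth_series.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a session bundle from a directory
#'
#' Validates the bundle: spike times are re-sorted per unit (with a
#' warning) if out of order, event times must be strictly increasing, and
#' the tracking must be uniform 50 Hz -- non-uniform timestamps are
#' re-interpolated onto a uniform grid and gaps longer than 5 s are an
#' error.
#'
#' @param dir Directory containing the bundle.
#' @return An `hd_session` (with `truth` if the bundle carries it).
#' @export
load_session <- function(dir) {
  need <- c("spikes.tsv", "tracking.tsv", "events.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) stop("missing bundle file(s): ", paste(missing, collapse = ", "))
  spk <- utils::read.delim(file.path(dir, "spikes.tsv"), stringsAsFactors = FALSE)
  if (!all(c("unit_id", "region", "time_s") %in% names(spk)))
    stop("spikes.tsv must have unit_id, region, time_s columns")
  trk <- utils::read.delim(file.path(dir, "tracking.tsv"))
  if (!all(c("time_s", "hd_deg") %in% names(trk)))
    stop("tracking.tsv must have time_s, hd_deg columns")
  ev <- utils::read.delim(file.path(dir, "events.tsv"), stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character", "numeric"))
  if (nrow(ev) && any(diff(ev$time_s) <= 0))
    stop("events.tsv: times must be strictly increasing")
  if (nrow(ev) && !all(ev$event %in% c("rotate", "cue_off", "cue_on")))
    stop("events.tsv: unknown event type")

  dtv <- diff(trk$time_s)
  if (any(dtv <= 0)) stop("tracking.tsv: non-monotone timestamps")
  if (any(dtv > 5)) stop("tracking.tsv: gap longer than 5 s")
  dt <- 0.02
  if (max(abs(dtv - dt)) > 1e-6) {
    grid <- seq(trk$time_s[1], trk$time_s[nrow(trk)], by = dt)
    u <- unwrap_deg(trk$hd_deg)
    trk <- data.frame(time_s = grid,
                      hd_deg = stats::approx(trk$time_s, u, xout = grid)$y %% 360)
  }

  units <- unique(spk[, c("unit_id", "region")])
  units <- units[order(units$region, units$unit_id), ]
  rownames(units) <- units$unit_id
  spikes <- split(spk$time_s, spk$unit_id)[units$unit_id]
  unsorted <- vapply(spikes, function(x) is.unsorted(x, strictly = FALSE), logical(1))
  if (any(unsorted)) {
    warning("re-sorting spike times of ", sum(unsorted), " unit(s)")
    spikes[unsorted] <- lapply(spikes[unsorted], sort)
  }

  wf <- NULL; sr <- NULL
  wf_path <- file.path(dir, "waveforms.tsv")
  if (file.exists(wf_path)) {
    w <- utils::read.delim(wf_path)
    w <- w[match(units$unit_id, w$unit_id), ]
    sr <- w$sample_rate[1]
    wf <- as.matrix(w[, -(1:2)])
    rownames(wf) <- units$unit_id
  }

  truth <- NULL
  ty <- file.path(dir, "truth.yaml")
  ts <- file.path(dir, "truth_series.tsv")
  if (file.exists(ty)) {
    y <- yaml::read_yaml(ty)
    truth <- list(
      units = do.call(rbind, lapply(y$units, as.data.frame)),
      connections = if (length(y$connections))
        do.call(rbind, lapply(y$connections, as.data.frame))
      else data.frame(),
      wf_class = unlist(y$wf_class))
    if (file.exists(ts)) {
      s <- utils::read.delim(ts)
      truth$series_50hz <- s
    }
  }
  structure(list(units = units[, c("unit_id", "region")], spikes = spikes,
                 tracking = trk, events = ev, waveforms = wf,
                 wf_sample_rate = sr, truth = truth),
            class = "hd_session")
}

## ---------------------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Drives simulate -> HD classification -> decoding -> rotation
#' coordination -> connectivity -> waveform classing over one session, as
#' configured, and writes tidy TSV outputs, a JSON summary and a log
#' (including the seed and all tunable parameter values) to `out_dir`.
#' Reruns with the same configuration and seed produce byte-identical
#' numeric outputs.
#'
#' @param config A list or path to a YAML file. Recognized keys:
#'   `simulate` (arguments to [sim_config()]), `session_dir` (load an
#'   existing bundle instead of simulating), `stages` (subset of
#'   `c("tuning", "decoding", "connectivity", "waveforms")`),
#'   `train_window`, `test_window`, `segments` (list of two `c(start,
#'   end)` classification segments), `n_shuffle`, `lambda`. Unknown keys
#'   are rejected.
#' @param out_dir Output directory.
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return List of stage results, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "session_dir", "stages", "train_window",
             "test_window", "segments", "n_shuffle", "lambda")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key: ", bad[1])
  stages <- config$stages %||% c("tuning", "decoding", "connectivity", "waveforms")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  cat("", file = logf)
  logline("seed:", seed)

  if (!is.null(config$session_dir)) {
    session <- load_session(config$session_dir)
    logline("loaded session from", config$session_dir)
  } else {
    cfg <- do.call(sim_config, config$simulate %||% list())
    session <- simulate_session(cfg, seed = seed)
    write_session(session, file.path(out_dir, "session"))
    logline("simulated session: duration", cfg$duration, "s")
  }
  dur <- max(session$tracking$time_s)
  segments <- config$segments %||% list(c(0, dur / 2), c(dur / 2, dur))
  train_window <- config$train_window %||% c(0, max(120, min(300, dur / 2)))
  test_window <- config$test_window %||% c(train_window[2], dur)
  n_shuffle <- config$n_shuffle %||% 500
  lambda <- config$lambda %||% 1
  logline("parameters: n_shuffle", n_shuffle, "lambda", lambda,
          "smoothing 1 bin; shuffle min shift 20 s; ridge targets 10 deg bins")

  out <- list(session = session)
  summary <- list(seed = seed, n_units = table(session$units$region))

  if ("tuning" %in% stages) {
    set.seed(seed + 1L)
    hd <- lapply(session$units$unit_id, function(id) {
      cl <- tryCatch(
        classify_hd_unit(session$spikes[[id]], session$tracking,
                         rbind(segments[[1]]), rbind(segments[[2]]),
                         n_shuffle = n_shuffle),
        error = function(e) NULL)
      tc <- tryCatch(compute_tuning_curve(session$spikes[[id]], session$tracking,
                                          rbind(segments[[1]])),
                     error = function(e) NULL)
      met <- if (!is.null(tc) && tc$n_spikes > 0)
        .segment_metrics(session$spikes[[id]], session$tracking, rbind(segments[[1]]))
      else NULL
      data.frame(unit_id = id,
                 region = session$units$region[session$units$unit_id == id],
                 info = met$info %||% NA_real_, R = met$R %||% NA_real_,
                 kappa = met$kappa %||% NA_real_,
                 pfd_deg = met$pfd_deg %||% NA_real_,
                 n_peaks = met$n_peaks %||% NA_integer_,
                 label = cl$label %||% "unclassifiable",
                 is_hd = isTRUE(cl$is_hd))
    })
    hd <- do.call(rbind, hd)
    out$hd_metrics <- hd
    utils::write.table(hd, file.path(out_dir, "hd_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_hd <- table(hd$region[hd$is_hd])
    logline("tuning:", sum(hd$is_hd), "HD units")
  }

  if ("decoding" %in% stages) {
    for (r in intersect(c("A", "B"), unique(session$units$region))) {
      set.seed(seed + 2L)
      model <- tryCatch(hd_decoder(session, r, train_window, lambda = lambda),
                        error = function(e) {logline("decoder", r, "failed:",
                                                     conditionMessage(e)); NULL})
      if (is.null(model)) next
      traj <- predict(model)
      utils::write.table(
        data.frame(time_s = sprintf("%.3f", traj$time_s),
                   decoded_deg = sprintf("%.4f", traj$decoded_deg),
                   tracked_deg = sprintf("%.4f", traj$tracked_deg),
                   error_deg = sprintf("%.4f", traj$error_deg)),
        file.path(out_dir, paste0("decoded_", r, ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
      acc <- decoding_accuracy(traj, test_window)
      summary[[paste0("accuracy_", r)]] <- acc
      out[[paste0("decoder_", r)]] <- model
      logline("decoding region", r, ": accuracy", sprintf("%.1f deg", acc))
    }
  }

  if ("connectivity" %in% stages && all(c("A", "B") %in% session$units$region)) {
    set.seed(seed + 3L)
    hd_table <- if (!is.null(out$hd_metrics)) {
      data.frame(unit_id = out$hd_metrics$unit_id, is_hd = out$hd_metrics$is_hd,
                 pfd_deg = out$hd_metrics$pfd_deg)
    } else data.frame(unit_id = session$units$unit_id, is_hd = FALSE,
                      pfd_deg = NA_real_)
    census <- connection_census(session, hd_table)
    out$census <- census
    utils::write.table(census$connections,
                       file.path(out_dir, "connections.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$n_connections <- nrow(census$connections)
    logline("connectivity:", nrow(census$connections), "putative connections")
  }

  if ("waveforms" %in% stages && !is.null(session$waveforms)) {
    wf <- classify_session_waveforms(session)
    out$wf_classes <- wf
    utils::write.table(wf, file.path(out_dir, "waveform_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$hd_metrics)) {
      out$hd_metrics$wf_class <- wf$class[match(out$hd_metrics$unit_id, wf$unit_id)]
      utils::write.table(out$hd_metrics, file.path(out_dir, "hd_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$n_fs <- sum(wf$class == "FS")
    logline("waveforms:", sum(wf$class == "FS"), "FS /", sum(wf$class == "RS"), "RS")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
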