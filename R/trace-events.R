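#' Estimate the resting fluorescence baseline
#'
#' Removes a linear drift (fitted by least squares, level-preserving) and
#' then iteratively discards data points lying more than `sd_factor` times
#' the current standard deviation above the current mean, until the
#' retained SD changes by less than 1% between passes. The resting level
#' F0 is the mean of the retained points; the background SD is their
#' standard deviation.
#'
#' @param trace numeric vector of fluorescence values (one node), >= 20
#'   frames.
#' @param frame_rate frames per second (used only to express the drift per
#'   second).
#' @param sd_factor discard threshold in SDs above the mean (default 2).
#' @param max_iter safety bound on discard passes (default 50).
#' @return List of class `baseline_estimate`: `f0`, `background_sd`,
#'   `drift` (list with `slope_per_s`), `detrended` (the drift-corrected
#'   trace), `retained` (logical per frame).
#' @export
estimate_baseline <- function(trace, frame_rate = 33, sd_factor = 2,
                              max_iter = 50) {
  trace <- as.numeric(trace)
  if (length(trace) < 20L) stop("trace too short (< 20 frames)", call. = FALSE)
  tt <- seq_along(trace)
  keep <- rep(TRUE, length(trace))
  sd_prev <- Inf
  slope <- 0
  detrended <- trace
  for (it in seq_len(max_iter)) {
    # refit the drift on the currently retained points only, so transients
    # cannot tilt the baseline; remove the trend but keep the level
    fit <- stats::lm.fit(cbind(1, tt[keep]), trace[keep])
    slope <- unname(fit$coefficients[2L])
    if (!is.finite(slope)) slope <- 0
    detrended <- trace - slope * (tt - mean(tt[keep]))
    mu <- mean(detrended[keep])
    s <- stats::sd(detrended[keep])
    if (is.na(s)) break
    if (is.finite(sd_prev) && sd_prev > 0 && abs(s - sd_prev) / sd_prev < 0.01) break
    if (s == 0) break
    keep_new <- detrended <= mu + sd_factor * s
    if (sum(keep_new) < 10L) break  # keep the previous retention
    keep <- keep_new
    sd_prev <- s
  }
  if (sum(keep) < 10L) stop("degenerate trace: fewer than 10 baseline points", call. = FALSE)
  structure(list(f0 = mean(detrended[keep]),
                 background_sd = stats::sd(detrended[keep]),
                 drift = list(slope_per_s = slope * frame_rate),
                 detrended = detrended,
                 retained = keep),
            class = "baseline_estimate")
}

#' Normalize a trace to relative fluorescence
#'
#' Expresses the drift-corrected signal as (F - F0) / F0, the standard
#' relative fluorescence change. Invariant under an overall rescaling of
#' the raw trace.
#'
#' @param trace numeric fluorescence vector, or NULL to use the
#'   drift-corrected trace stored in `baseline`.
#' @param baseline a [estimate_baseline()] result.
#' @return Numeric vector of relative signal per frame.
#' @export
normalize_trace <- function(trace = NULL, baseline) {
  if (baseline$f0 <= 0) stop("F0 must be positive to normalize", call. = FALSE)
  f <- if (is.null(trace)) baseline$detrended else as.numeric(trace)
  (f - baseline$f0) / baseline$f0
}

#' Detect ignition onsets in a normalized trace
#'
#' An onset is declared where the (boxcar-smoothed) signal exceeds
#' `sd_factor` times the background SD for at least `min_frames`
#' consecutive frames, accompanied by a maximum of the signal derivative at
#' the start of the excursion -- the fast rise of a calcium transient. The
#' onset frame is the last frame at baseline before the threshold
#' crossing. Events closer than `min_frames` frames are merged (first
#' kept); a flat trace yields no events.
#'
#' @param norm_signal normalized signal from [normalize_trace()].
#' @param background_sd_norm background SD on the normalized scale.
#' @param frame_rate frames per second (default 33).
#' @param sd_factor threshold in background SDs (default 2).
#' @param min_frames minimum frames above threshold (default 5).
#' @param smooth_window boxcar window (frames) applied before
#'   differentiation (default 3).
#' @param node_id id stored in the returned events (default "1").
#' @return Data frame with one row per event: `node_id`, `frame` (0-based
#'   onset frame), `time` (seconds), `refined` (FALSE here; see
#'   [refine_onset_subframe()]).
#' @export
detect_onsets <- function(norm_signal, background_sd_norm, frame_rate = 33,
                          sd_factor = 2, min_frames = 5, smooth_window = 3,
                          node_id = "1") {
  x <- as.numeric(norm_signal)
  n <- length(x)
  empty <- data.frame(node_id = character(0), frame = integer(0),
                      time = numeric(0), refined = logical(0),
                      stringsAsFactors = FALSE)
  if (n < min_frames + 2L) return(empty)
  if (smooth_window > 1L) {
    sm <- as.numeric(stats::filter(x, rep(1 / smooth_window, smooth_window),
                                   sides = 2L))
    sm[is.na(sm)] <- x[is.na(sm)]
  } else sm <- x
  thr <- sd_factor * background_sd_norm
  above <- sm > thr
  if (!any(above)) return(empty)
  d <- c(0, diff(sm))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_frames)
  frames <- integer(0)
  last_accept <- -Inf
  for (k in cand) {
    s <- starts[k]
    # require a derivative maximum near the excursion start
    win <- s:min(n, s + min_frames)
    if (max(d[win]) <= 0) next
    # a genuine ignition rises from baseline: the frames just before the
    # crossing must sit clearly below threshold (rejects re-crossings of
    # a decaying transient's tail)
    pre <- max(1L, s - 2L * min_frames):(s - 1L)
    if (s > 1L && mean(sm[pre]) > thr / 2) next
    # hysteresis: after an accepted event the detector re-arms only once
    # the signal has returned to within one background SD of baseline
    if (is.finite(last_accept)) {
      between <- sm[last_accept:s]
      if (min(between) > thr / sd_factor) next
    }
    # smoothing pulls the crossing early; locate the last frame at or
    # below threshold on the raw signal
    j <- s
    while (j < n && j < s + min_frames && x[j] <= thr) j <- j + 1L
    onset <- max(1L, j - 1L)
    frames <- c(frames, onset)
    last_accept <- s
  }
  if (!length(frames)) return(empty)
  frames <- sort(frames)
  keep <- c(TRUE, diff(frames) >= min_frames)
  frames <- frames[keep]
  data.frame(node_id = node_id, frame = frames - 1L,
             time = (frames - 1L) / frame_rate, refined = FALSE,
             stringsAsFactors = FALSE)
}

#' Refine an onset time to sub-frame resolution
#'
#' Fits one least-squares line through the `n_background` baseline points
#' preceding the detected onset and another through the `n_rise` points of
#' the fast rise that follows it; the abscissa of their crossing is the
#' refined onset time. If the two lines are near-parallel, or there are
#' too few frames on either side, the unrefined frame time is returned
#' with `refined = FALSE`.
#'
#' @param norm_signal normalized signal vector.
#' @param onset_frame 0-based onset frame from [detect_onsets()].
#' @param frame_rate frames per second (default 33).
#' @param n_background baseline points before the onset (default 10).
#' @param n_rise rise points after the onset (default 5).
#' @return List with `time` (seconds) and `refined` (logical).
#' @export
refine_onset_subframe <- function(norm_signal, onset_frame, frame_rate = 33,
                                  n_background = 10, n_rise = 5) {
  x <- as.numeric(norm_signal)
  f <- onset_frame + 1L  # 1-based index of the onset frame
  frame_time <- onset_frame / frame_rate
  if (f - n_background < 1L || f + n_rise > length(x)) {
    return(list(time = frame_time, refined = FALSE))
  }
  ib <- (f - n_background):f
  ir <- (f + 1L):(f + n_rise)
  tb <- (ib - 1L) / frame_rate
  tr <- (ir - 1L) / frame_rate
  cb <- stats::lm.fit(cbind(1, tb), x[ib])$coefficients
  cr <- stats::lm.fit(cbind(1, tr), x[ir])$coefficients
  dslope <- cr[2L] - cb[2L]
  scale <- max(abs(cr[2L]), abs(cb[2L]), 1 / frame_rate)
  if (!is.finite(dslope) || abs(dslope) < 1e-8 * scale) {
    return(list(time = frame_time, refined = FALSE))
  }
  t_cross <- unname((cb[1L] - cr[1L]) / dslope)
  if (!is.finite(t_cross) || abs(t_cross - frame_time) > 1 / frame_rate) {
    return(list(time = frame_time, refined = FALSE))
  }
  list(time = t_cross, refined = TRUE)
}

#' Extract onset events from a trace matrix
#'
#' Full per-node pipeline: baseline estimation, normalization, onset
#' detection, and (optionally) sub-frame refinement, applied to every
#' column of a frames x nodes trace matrix.
#'
#' @param traces numeric matrix (frames x nodes); column names are node
#'   ids; attribute `frame_rate` is used unless `frame_rate` is given.
#' @param frame_rate frames per second.
#' @param refine logical, apply [refine_onset_subframe()] (default TRUE).
#' @param ... passed to [detect_onsets()].
#' @inheritParams refine_onset_subframe
#' @return An [event_train()] over the matrix's nodes, with a `refined`
#'   attribute vector aligned to the events.
#' @export
detect_events <- function(traces, frame_rate = attr(traces, "frame_rate"),
                          refine = TRUE, n_background = 10, n_rise = 5, ...) {
  if (is.null(frame_rate)) stop("frame rate unknown", call. = FALSE)
  ids <- colnames(traces)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(traces)))
  rows <- list()
  for (j in seq_len(ncol(traces))) {
    bl <- estimate_baseline(traces[, j], frame_rate = frame_rate)
    ns <- normalize_trace(baseline = bl)
    ev <- detect_onsets(ns, bl$background_sd / bl$f0, frame_rate = frame_rate,
                        node_id = ids[j], ...)
    if (refine && nrow(ev)) {
      for (e in seq_len(nrow(ev))) {
        rf <- refine_onset_subframe(ns, ev$frame[e], frame_rate,
                                    n_background, n_rise)
        ev$time[e] <- rf$time
        ev$refined[e] <- rf$refined
      }
    }
    rows[[j]] <- ev
  }
  all_ev <- do.call(rbind, rows)
  train <- event_train(all_ev$node_id, all_ev$time, nodes = ids)
  ord <- order(all_ev$time, all_ev$node_id)
  attr(train, "refined") <- all_ev$refined[ord]
  train
}
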