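#' Force-ramp description for a magnetic-tweezer cycle
#'
#' @param load_rate_pN_s Loading rate during the pull (default +1 pN/s).
#' @param release_rate_pN_s Rate during release (default -0.1 pN/s).
#' @param f_start,f_end Force range of the pull, pN.
#' @param sample_dt_s Sampling interval (default 0.01 s, the temporal
#'   resolution of the setup).
#' @return A list of class `force_ramp`.
#' @export
force_ramp <- function(load_rate_pN_s = 1, release_rate_pN_s = -0.1,
                       f_start = 1, f_end = 20, sample_dt_s = 0.01) {
  stopifnot(f_start < f_end, sample_dt_s > 0, load_rate_pN_s > 0,
            release_rate_pN_s < 0)
  structure(list(load_rate_pN_s = load_rate_pN_s,
                 release_rate_pN_s = release_rate_pN_s,
                 f_start = f_start, f_end = f_end,
                 sample_dt_s = sample_dt_s),
            class = "force_ramp")
}

validate_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "force_pN", "height_nm") %in% names(trace)))
  if (any(diff(trace$time_s) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  invisible(trace)
}

#' Detect stepwise bead-height transitions in a force-ramp trace
#'
#' Change-point detection by a two-sided sliding-window mean-difference
#' statistic: at each sample the means of the `window` samples before and
#' after are compared; local extrema of the difference that exceed both
#' `min_step_nm` and `significance` times the local noise SD (estimated
#' robustly from first differences) are reported as events. The step size
#' is the difference of the flanking plateau levels at the change point,
#' each estimated by a linear fit over its window (the detrending removes
#' the smooth force-ramp baseline drift from the estimate); the event force
#' is the force at the change point. Extrema closer than one window are
#' merged (largest statistic wins).
#'
#' @param trace Data frame with `time_s`, `force_pN`, `height_nm`.
#' @param window Plateau window length in samples.
#' @param significance Threshold in units of the noise SD of the windowed
#'   mean difference.
#' @param min_step_nm Minimum reportable step size, nm.
#' @return Tibble of events sorted by time: `time_s`, `force_pN`,
#'   `force_err_pN`, `delta_h_nm` (signed; positive = upward).
#' @export
detect_steps <- function(trace, window = 30, significance = 6,
                         min_step_nm = 10) {
  validate_trace(trace)
  h <- trace$height_nm
  n <- length(h)
  if (n < 2 * window + 1) {
    stop("trace shorter than two detection windows", call. = FALSE)
  }
  cs <- c(0, cumsum(h))
  i <- seq(window + 1, n - window)        # candidate change points: step between i and i+1...
  after <- (cs[i + window + 1] - cs[i + 1]) / window
  before <- (cs[i + 1] - cs[i - window + 1]) / window
  stat <- after - before
  # robust noise scale of the raw signal -> scale of the mean-difference stat
  noise_sd <- stats::mad(diff(h)) / sqrt(2)
  thr <- max(min_step_nm, significance * noise_sd * sqrt(2 / window))
  cand <- which(abs(stat) >= thr)
  if (length(cand) == 0) {
    return(tibble::tibble(time_s = numeric(), force_pN = numeric(),
                          force_err_pN = numeric(), delta_h_nm = numeric()))
  }
  # group candidates separated by less than one window; keep the extremum
  grp <- cumsum(c(1, diff(cand) > window))
  picks <- vapply(split(cand, grp), function(ix) {
    ix[which.max(abs(stat[ix]))]
  }, numeric(1))
  picks <- sort(picks)
  idx <- i[picks]                         # last sample of the pre-step plateau
  # detrended step size: linear fit on each flanking window, both
  # extrapolated to the change point (midway between idx and idx + 1)
  dh <- vapply(idx, function(t0) {
    xb <- seq(-window + 1, 0); yb <- h[t0 + xb]
    xa <- seq(1, window); ya <- h[t0 + xa]
    cb <- stats::lm.fit(cbind(1, xb), yb)$coefficients
    ca <- stats::lm.fit(cbind(1, xa), ya)$coefficients
    unname((ca[1] + ca[2] * 0.5) - (cb[1] + cb[2] * 0.5))
  }, numeric(1))
  ev <- tibble::tibble(
    time_s = trace$time_s[idx],
    force_pN = trace$force_pN[idx],
    force_err_pN = force_error(trace$force_pN[idx]),
    delta_h_nm = dh
  )
  ev[order(ev$time_s), ]
}

#' Classify a dissociation/unfolding step by its size and force
#'
#' Attribution rule: steps of at most 35 nm are not attributed to
#' dissociation of the VBS--VD1 complex (`below_threshold`; isolated VD1
#' subunit unfolding produces ~35 nm steps). Larger steps are assigned the
#' scenario whose predicted band (scenario prediction +/- `band_tol_nm`)
#' contains the observed step at the observed force; anything above the
#' full-unfold prediction is `unloop_full_unfold`. If bands overlap, the
#' scenario with fewer released segments wins (parsimony tie-break); a step
#' falling between bands is assigned the nearest band.
#'
#' @param delta_h_nm Observed step size(s), nm, > 0.
#' @param force_pN Force(s) at the transition, pN.
#' @param construct A [construct_model()].
#' @param params A [wlc_params()].
#' @param threshold_nm Dissociation attribution threshold (35 nm).
#' @param band_tol_nm Half-width added around each scenario prediction.
#' @return Character vector of classes: `below_threshold`, `unloop_only`,
#'   `unloop_partial_unfold`, `unloop_full_unfold`.
#' @examples
#' classify_step(120, 16)
#' classify_step(45, 10)
#' @export
classify_step <- function(delta_h_nm, force_pN, construct = construct_model(),
                          params = wlc_params(), threshold_nm = 35,
                          band_tol_nm = 10) {
  stopifnot(all(delta_h_nm > 0), length(delta_h_nm) == length(force_pN))
  scen <- c("unloop_only", "unloop_partial_unfold", "unloop_full_unfold")
  mapply(function(dh, f) {
    if (dh <= threshold_nm) return("below_threshold")
    pred <- vapply(scen, predicted_step, numeric(1),
                   force_pN = f, construct = construct, params = params)
    if (dh >= pred["unloop_full_unfold"]) return("unloop_full_unfold")
    inside <- which(abs(dh - pred) <= band_tol_nm)
    if (length(inside) > 0) return(scen[inside[1]])   # fewest released segments
    scen[which.min(abs(dh - pred))]
  }, delta_h_nm, force_pN, USE.NAMES = FALSE)
}

#' Detect and classify all rupture events in a tweezer trace
#'
#' Convenience wrapper: [detect_steps()] on the trace, keep upward steps,
#' then [classify_step()] each event.
#'
#' @inheritParams detect_steps
#' @inheritParams classify_step
#' @param keep_downward Keep downward (refolding/relooping) steps, labelled
#'   `NA` class. Default drops them.
#' @return Tibble of events with an `event_class` column.
#' @export
analyze_tweezer_trace <- function(trace, window = 30, significance = 6,
                                  min_step_nm = 10,
                                  construct = construct_model(),
                                  params = wlc_params(),
                                  threshold_nm = 35, band_tol_nm = 10,
                                  keep_downward = FALSE) {
  ev <- detect_steps(trace, window, significance, min_step_nm)
  if (!keep_downward) ev <- ev[ev$delta_h_nm > 0, ]
  ev$event_class <- if (nrow(ev) == 0) character(0) else
    ifelse(ev$delta_h_nm > 0,
           classify_step(abs(ev$delta_h_nm), ev$force_pN, construct, params,
                         threshold_nm, band_tol_nm),
           NA_character_)
  ev
}
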