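#' Double normalization of a FRAP trace
#'
#' Corrects the bleached-ROI recovery curve for acquisition photobleaching
#' and background:
#' \deqn{I_{norm}(t) = \frac{Iref_{pre}}{Iref(t) - Iback(t)} \cdot
#'       \frac{Ifrap(t) - Iback(t)}{Ifrap_{pre}}}
#' where the `pre` terms are averages over all frames strictly before the
#' bleach, after background subtraction.
#'
#' @param trace Data frame with columns `time_s`, `i_frap`, `i_ref`,
#'   `i_back` (background may be constant or per-frame).
#' @param bleach_index Number of pre-bleach frames: the bleach is applied
#'   after frame `bleach_index`, so frames `1:bleach_index` are pre-bleach
#'   and frame `bleach_index + 1` is the bleach frame. Default 4 (bleach
#'   after the fourth acquisition).
#' @return The input as a tibble with an `i_norm` column.
#' @export
frap_double_normalize <- function(trace, bleach_index = 4) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "i_frap", "i_ref", "i_back") %in% names(trace)))
  n <- nrow(trace)
  stopifnot(bleach_index >= 1, bleach_index < n)
  if (!all(is.finite(trace$i_frap)) || !all(is.finite(trace$i_ref)) ||
      !all(is.finite(trace$i_back))) {
    stop("intensities must be finite", call. = FALSE)
  }
  pre <- seq_len(bleach_index)
  ref_bs <- trace$i_ref - trace$i_back
  frap_bs <- trace$i_frap - trace$i_back
  bad <- which(ref_bs <= 0)
  if (length(bad) > 0) {
    stop("reference intensity does not exceed background at frame(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  i_ref_pre <- mean(ref_bs[pre])
  i_frap_pre <- mean(frap_bs[pre])
  if (abs(i_frap_pre) < .Machine$double.eps) {
    stop("pre-bleach FRAP intensity is zero", call. = FALSE)
  }
  out <- tibble::as_tibble(trace)
  out$i_norm <- (i_ref_pre / ref_bs) * (frap_bs / i_frap_pre)
  attr(out, "bleach_index") <- bleach_index
  out
}

#' Full-scale calibration of a double-normalized FRAP trace
#'
#' Rescales `i_norm` so the pre-bleach average maps to 1 and the bleach
#' frame to 0:
#' \deqn{I_{norm1}(t) = \frac{I_{norm}(t) - I_{norm}(t_{bleach})}
#'       {I_{norm,pre} - I_{norm}(t_{bleach})}.}
#' The bleach frame is taken as the first frame after `bleach_index`
#' pre-bleach frames.
#'
#' @param trace Output of [frap_double_normalize()] (has `i_norm`).
#' @param bleach_index Number of pre-bleach frames; defaults to the value
#'   recorded by [frap_double_normalize()].
#' @return The tibble with an `i_norm1` column.
#' @export
frap_full_scale <- function(trace, bleach_index = attr(trace, "bleach_index")) {
  stopifnot("i_norm" %in% names(trace), !is.null(bleach_index))
  pre <- seq_len(bleach_index)
  i_norm_pre <- mean(trace$i_norm[pre])
  v_bleach <- trace$i_norm[bleach_index + 1]
  depth <- i_norm_pre - v_bleach
  if (abs(depth) < 1e-12) {
    stop("zero bleach depth: full-scale calibration undefined", call. = FALSE)
  }
  out <- tibble::as_tibble(trace)
  out$i_norm1 <- (trace$i_norm - v_bleach) / depth
  attr(out, "bleach_index") <- bleach_index
  out
}

#' Normalize a FRAP trace (double normalization then full scale)
#'
#' @inheritParams frap_double_normalize
#' @return Tibble with `i_norm` and `i_norm1` columns.
#' @export
frap_normalize <- function(trace, bleach_index = 4) {
  frap_full_scale(frap_double_normalize(trace, bleach_index))
}

#' Fit the single-exponential recovery model
#'
#' Fits `I(t) = p (1 - exp(-k t))` to the full-scale-normalized recovery,
#' with `t` measured from the bleach frame, by bounded
#' Levenberg--Marquardt least squares. The plateau `p` is the mobile
#' fraction relative to total (the full-scale curve saturates at 1 for a
#' fully mobile pool) and the half-life is `ln 2 / k`.
#'
#' @param trace Output of [frap_normalize()] / [frap_full_scale()], or any
#'   data frame with `time_s` and `i_norm1`.
#' @param bleach_index Number of pre-bleach frames.
#' @return An object of class `frap_fit`; see [tidy.frap_fit()] and
#'   [glance.frap_fit()].
#' @examples
#' tr <- sim_frap_trace(p = 0.4, k = log(2) / 25, noise_sd = 0, seed = 1)
#' fit <- fit_frap_recovery(frap_normalize(tr$trace))
#' glance(fit)
#' @export
fit_frap_recovery <- function(trace, bleach_index = attr(trace, "bleach_index")) {
  stopifnot("i_norm1" %in% names(trace), !is.null(bleach_index))
  post <- seq(bleach_index + 1, nrow(trace))
  if (length(post) < 5) stop("need at least 5 post-bleach frames", call. = FALSE)
  tt <- trace$time_s[post] - trace$time_s[bleach_index + 1]
  yy <- trace$i_norm1[post]
  # initialization: plateau from the last quartile, rate from the time to
  # reach half the plateau
  p0 <- mean(yy[tt >= stats::quantile(tt, 0.75)])
  p0 <- min(max(p0, 0.01), 1.5)
  t_half_guess <- tt[which(yy >= p0 / 2)[1]]
  k0 <- if (is.na(t_half_guess) || t_half_guess <= 0) 0.05 else log(2) / t_half_guess
  k0 <- min(max(k0, 1e-4), 10)
  df <- data.frame(tt = tt, yy = yy)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ p * (1 - exp(-k * tt)), data = df,
                      start = list(p = p0, k = k0),
                      lower = c(0, 1e-6), upper = c(1.5, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(p = NA_real_, k = NA_real_, half_life_s = NA_real_,
                residual_ss = NA_real_, converged = FALSE,
                k_at_bound = NA, p_flagged = NA,
                ci = NULL, n_post = length(post))
    class(out) <- "frap_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  ci <- tryCatch(suppressMessages(stats::confint.default(fit)),
                 error = function(e) NULL)
  out <- list(p = unname(cf["p"]), k = unname(cf["k"]),
              half_life_s = log(2) / unname(cf["k"]),
              residual_ss = sum(stats::resid(fit)^2),
              converged = fit$convInfo$isConv %||% TRUE,
              k_at_bound = unname(cf["k"]) >= 10 - 1e-8 || unname(cf["k"]) <= 2e-6,
              p_flagged = unname(cf["p"]) > 1,
              ci = ci, n_post = length(post))
  class(out) <- "frap_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>  p =", signif(x$p, 4), " k =", signif(x$k, 4),
      "1/s  half-life =", signif(x$half_life_s, 4), "s\n")
  invisible(x)
}

#' Tidy a FRAP recovery fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`p`, `k`) and confidence
#'   bounds where available.
#' @export
tidy.frap_fit <- function(x, ...) {
  ci <- x$ci
  tibble::tibble(
    term = c("p", "k"),
    estimate = c(x$p, x$k),
    conf.low = if (is.null(ci)) c(NA_real_, NA_real_) else ci[, 1],
    conf.high = if (is.null(ci)) c(NA_real_, NA_real_) else ci[, 2]
  )
}

#' One-row summary of a FRAP recovery fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One-row tibble: mobile fraction, rate, half-life, residual SS,
#'   convergence and bound flags.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(mobile_fraction = x$p, k = x$k, half_life_s = x$half_life_s,
                 residual_ss = x$residual_ss, converged = x$converged,
                 k_at_bound = x$k_at_bound, p_above_one = x$p_flagged,
                 n_post = x$n_post)
}

#' Plot a normalized FRAP recovery with its fitted curve
#'
#' @param object A `frap_fit`.
#' @param trace The normalized trace the fit was made from.
#' @param bleach_index Number of pre-bleach frames.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_fit <- function(object, trace, bleach_index = attr(trace, "bleach_index"), ...) {
  post <- seq(bleach_index + 1, nrow(trace))
  t0 <- trace$time_s[bleach_index + 1]
  df <- tibble::tibble(time_s = trace$time_s, i_norm1 = trace$i_norm1)
  curve <- tibble::tibble(
    time_s = seq(t0, max(trace$time_s), length.out = 200))
  curve$i_norm1 <- object$p * (1 - exp(-object$k * (curve$time_s - t0)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$i_norm1)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "time (s)", y = "normalized intensity")
}

#' Compare recovery fits across experimental conditions
#'
#' Per-condition summaries of mobile fraction and half-life plus ordinary
#' one-way ANOVA (no multiple-comparison correction) on each quantity.
#'
#' @param fits Data frame with columns `condition`, `mobile_fraction`,
#'   `half_life_s` (e.g. row-bound [glance.frap_fit()] outputs).
#' @return List with `summary` (per-condition tibble) and `anova` (tibble
#'   with F and p for each quantity).
#' @export
summarize_frap_groups <- function(fits) {
  stopifnot(all(c("condition", "mobile_fraction", "half_life_s") %in% names(fits)))
  counts <- table(fits$condition)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 conditions with >= 2 fits each", call. = FALSE)
  }
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fits), .data$condition),
    n = dplyr::n(),
    mean_p = mean(.data$mobile_fraction), sd_p = stats::sd(.data$mobile_fraction),
    sem_p = .data$sd_p / sqrt(.data$n),
    mean_half_life_s = mean(.data$half_life_s),
    sd_half_life_s = stats::sd(.data$half_life_s),
    sem_half_life_s = .data$sd_half_life_s / sqrt(.data$n),
    .groups = "drop")
  one <- function(y) {
    a <- stats::anova(stats::aov(y ~ factor(fits$condition)))
    tibble::tibble(F = a$`F value`[1], p.value = a$`Pr(>F)`[1])
  }
  an <- dplyr::bind_rows(
    dplyr::mutate(one(fits$mobile_fraction), quantity = "mobile_fraction"),
    dplyr::mutate(one(fits$half_life_s), quantity = "half_life_s"))
  list(summary = summ, anova = an[, c("quantity", "F", "p.value")])
}
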