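#' Filter a velocity field by minimum speed
#'
#' Vectors slower than `threshold` are removed to suppress motion noise;
#' speeds exactly at the threshold are retained ("below" read strictly).
#'
#' @param field Data frame with columns `u_um_h`, `v_um_h` (and anything
#'   else, carried through); an optional logical `valid` column restricts
#'   the retained set first.
#' @param threshold Speed cutoff in um/h (default 10).
#' @return Tibble of retained vectors with a `speed_um_h` column.
#' @export
speed_filter <- function(field, threshold = 10) {
  stopifnot(all(c("u_um_h", "v_um_h") %in% names(field)))
  out <- tibble::as_tibble(field)
  if ("valid" %in% names(out)) out <- out[out$valid %in% TRUE, ]
  out$speed_um_h <- sqrt(out$u_um_h^2 + out$v_um_h^2)
  out[out$speed_um_h >= threshold, ]
}

#' Angular distribution of a migration velocity field
#'
#' Bins retained vector directions (`atan2(v, u)`, 0 degrees = outward
#' wound normal = +x) into 30-degree bins. The angular frequency of a bin
#' is its count over the total retained count; the relative angular speed
#' is frequency times the mean retained speed in the bin, so the relative
#' angular speeds sum to the overall mean retained speed.
#'
#' By default bin edges are offset by half a bin (-15, 15, 45, ... degrees)
#' so that 0 degrees is a bin center; set `center_zero = FALSE` for
#' edge-aligned bins at -180, -150, ... Bins are half-open `[edge, edge + 30)`.
#'
#' @param fields Data frame of vectors (one or several frames pooled), with
#'   `u_um_h`, `v_um_h`; typically pre-filtered with [speed_filter()], else
#'   `filter_threshold` is applied here.
#' @param bin_deg Bin width in degrees (default 30; must divide 360).
#' @param center_zero Offset edges by half a bin so 0 is a bin center.
#' @param filter_threshold Speed filter applied if no `speed_um_h` present.
#' @return Tibble with one row per bin: `bin_start_deg`, `bin_end_deg`,
#'   `bin_center_deg`, `n`, `frequency`, `mean_speed_um_h`,
#'   `relative_angular_speed_um_h`.
#' @export
angular_distribution <- function(fields, bin_deg = 30, center_zero = TRUE,
                                 filter_threshold = 10) {
  stopifnot(360 %% bin_deg == 0)
  if (!"speed_um_h" %in% names(fields)) {
    fields <- speed_filter(fields, filter_threshold)
  }
  if (nrow(fields) == 0) {
    stop("no vectors retained after speed filtering", call. = FALSE)
  }
  ang <- atan2(fields$v_um_h, fields$u_um_h) * 180 / pi   # [-180, 180]
  offset <- if (center_zero) bin_deg / 2 else 0
  # wrap into [-180 - offset, 180 - offset) so every half-open bin is full
  ang <- ((ang + 180 + offset) %% 360) - 180 - offset
  edges <- seq(-180 - offset, 180 - offset, by = bin_deg)
  bin <- findInterval(ang, edges, rightmost.closed = FALSE, left.open = FALSE)
  total <- length(ang)
  speed <- fields$speed_um_h
  out <- tibble::tibble(bin_start_deg = edges[-length(edges)],
                        bin_end_deg = edges[-1],
                        bin_center_deg = edges[-length(edges)] + bin_deg / 2)
  out$n <- vapply(seq_len(nrow(out)), function(i) sum(bin == i), integer(1))
  out$frequency <- out$n / total
  out$mean_speed_um_h <- vapply(seq_len(nrow(out)), function(i) {
    if (out$n[i] == 0) 0 else mean(speed[bin == i])
  }, numeric(1))
  out$relative_angular_speed_um_h <- out$frequency * out$mean_speed_um_h
  out
}

#' Major angular component by Gaussian fit
#'
#' Fits `Y = Amplitude * exp(-0.5 * ((X - Mean) / SD)^2)` to the angular
#' frequency histogram by nonlinear least squares. Bins are first shifted
#' circularly so the modal bin sits at the center of the axis (the
#' histogram is periodic; the fit is done on the unwrapped axis) and the
#' fitted mean is reported wrapped into `[-180, 180)`.
#'
#' @param dist Output of [angular_distribution()].
#' @param min_nonzero_bins Minimum number of nonzero bins required.
#' @return Object of class `angular_fit` with `amplitude`, `mean_deg`,
#'   `sd_deg`, `residual_ss`, `converged`.
#' @export
gaussian_major_angle <- function(dist, min_nonzero_bins = 4) {
  stopifnot(all(c("bin_center_deg", "frequency") %in% names(dist)))
  if (sum(dist$frequency > 0) < min_nonzero_bins) {
    stop("need at least ", min_nonzero_bins, " nonzero bins", call. = FALSE)
  }
  k <- nrow(dist)
  bin_deg <- dist$bin_end_deg[1] - dist$bin_start_deg[1]
  modal <- which.max(dist$frequency)
  # unwrap the periodic axis so the modal bin sits at its center
  rel <- ((seq_len(k) - modal + floor(k / 2)) %% k) - floor(k / 2)
  x <- dist$bin_center_deg[modal] + rel * bin_deg
  y <- dist$frequency
  df <- data.frame(x = x, y = y)
  a0 <- max(y)
  m0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum(y * (x - m0)^2) / sum(y))
  s0 <- min(max(s0, bin_deg / 2), 180)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-0.5 * ((x - m) / s)^2), data = df,
                      start = list(A = a0, m = m0, s = s0),
                      lower = c(1e-9, m0 - 180, bin_deg / 10),
                      upper = c(10, m0 + 180, 360),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(amplitude = NA_real_, mean_deg = NA_real_, sd_deg = NA_real_,
                residual_ss = NA_real_, converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    mean_wrapped <- ((cf[["m"]] + 180) %% 360) - 180
    out <- list(amplitude = cf[["A"]], mean_deg = mean_wrapped,
                sd_deg = cf[["s"]], residual_ss = sum(stats::resid(fit)^2),
                converged = TRUE)
  }
  class(out) <- "angular_fit"
  out
}

#' @export
print.angular_fit <- function(x, ...) {
  cat("<angular_fit>  mean =", signif(x$mean_deg, 4), "deg  sd =",
      signif(x$sd_deg, 4), "deg  amplitude =", signif(x$amplitude, 4), "\n")
  invisible(x)
}

#' @rdname gaussian_major_angle
#' @param x An `angular_fit`.
#' @param ... Unused.
#' @export
tidy.angular_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "mean_deg", "sd_deg"),
                 estimate = c(x$amplitude, x$mean_deg, x$sd_deg))
}

#' Compare major migration angles across conditions
#'
#' One-way ANOVA on the per-experiment fitted major angles with Tukey HSD
#' pairwise comparisons.
#'
#' @param fits Data frame with columns `condition`, `mean_deg`.
#' @return List with `summary`, `anova`, and `pairwise` (Tukey-adjusted).
#' @export
compare_major_angles <- function(fits) {
  stopifnot(all(c("condition", "mean_deg") %in% names(fits)))
  counts <- table(fits$condition)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need >= 2 conditions with >= 2 fits each", call. = FALSE)
  }
  fits$condition <- factor(fits$condition)
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fits), .data$condition),
    n = dplyr::n(), mean_angle_deg = mean(.data$mean_deg),
    sd_deg = stats::sd(.data$mean_deg), .groups = "drop")
  fit <- stats::aov(mean_deg ~ condition, data = fits)
  a <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$condition
  pw <- tibble::tibble(comparison = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"])
  list(summary = summ,
       anova = tibble::tibble(F = a$`F value`[1], p.value = a$`Pr(>F)`[1]),
       pairwise = pw)
}

#' Rose plot of an angular distribution
#'
#' @param dist Output of [angular_distribution()].
#' @param value Column to plot (`"frequency"` or
#'   `"relative_angular_speed_um_h"`).
#' @return A ggplot object in polar coordinates.
#' @export
plot_rose <- function(dist, value = c("frequency", "relative_angular_speed_um_h")) {
  value <- match.arg(value)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin_center_deg,
                                     y = .data[[value]])) +
    ggplot2::geom_col(width = dist$bin_end_deg[1] - dist$bin_start_deg[1],
                      fill = "steelblue", colour = "grey30") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 150, by = 30)) +
    ggplot2::labs(x = NULL, y = value)
}

#' Segment tissue from a phase-contrast frame by local variance
#'
#' Pixels whose local intensity variance (over a square window) exceeds
#' `threshold` times the global variance are tissue; the largest connected
#' component is retained.
#'
#' @param image Numeric matrix.
#' @param window Odd window size in pixels.
#' @param threshold Fraction of the global variance.
#' @return Logical matrix mask.
#' @export
segment_tissue <- function(image, window = 9, threshold = 0.5) {
  stopifnot(is.matrix(image), window %% 2 == 1)
  gv <- stats::var(as.vector(image))
  if (gv < 1e-18) stop("uniform image: no texture to segment", call. = FALSE)
  m1 <- box_mean(image, window)
  m2 <- box_mean(image^2, window)
  lv <- pmax(m2 - m1^2, 0)
  mask <- lv > threshold * gv
  if (!any(mask)) stop("segmentation produced an empty mask", call. = FALSE)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(mask)
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  mask
}

# separable box filter via padded cumulative sums
box_mean <- function(x, w) {
  half <- (w - 1) / 2
  pad_apply <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1, half), , drop = FALSE], m,
                m[rep(n, half), , drop = FALSE])
    cs <- apply(mp, 2, cumsum)
    (rbind(cs[(w):(n + w - 1), , drop = FALSE]) -
        rbind(matrix(0, 1, ncol(m)), cs[seq_len(n - 1), , drop = FALSE])) / w
  }
  t(pad_apply(t(pad_apply(x))))
}

#' Minimal block-matching velocimetry on an image pair
#'
#' For each interrogation window, the displacement is the arg-max of the
#' normalized cross-correlation with the corresponding search region of the
#' second frame, converted to um/h via the pixel size and frame interval.
#' A stand-in for full-featured PIV, used to exercise the pipeline on
#' synthetic movies.
#'
#' @param frame_a,frame_b Numeric matrices of equal size.
#' @param window Interrogation window size in px.
#' @param overlap Fractional window overlap (0.5 = half-step).
#' @param dt_h Frame interval in hours.
#' @param px_um Pixel size in um.
#' @param max_shift Maximum displacement searched, px.
#' @return Tibble: `x_um`, `y_um` (window centers), `u_um_h`, `v_um_h`,
#'   `valid` (FALSE for featureless windows).
#' @export
block_velocimetry <- function(frame_a, frame_b, window = 32, overlap = 0.5,
                              dt_h = 1 / 3, px_um = 1, max_shift = 8) {
  stopifnot(all(dim(frame_a) == dim(frame_b)), window <= min(dim(frame_a)))
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  rs <- seq(1, nr - window + 1, by = step)
  cs <- seq(1, nc - window + 1, by = step)
  res <- list()
  for (r0 in rs) for (c0 in cs) {
    a <- frame_a[r0:(r0 + window - 1), c0:(c0 + window - 1)]
    if (stats::sd(a) < 1e-12) {
      res[[length(res) + 1]] <- c(r0, c0, NA, NA, 0)
      next
    }
    best <- c(0, 0); best_cc <- -Inf
    a0 <- a - mean(a); sa <- sqrt(sum(a0^2))
    for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
      r1 <- r0 + dr; c1 <- c0 + dc
      if (r1 < 1 || c1 < 1 || r1 + window - 1 > nr || c1 + window - 1 > nc) next
      b <- frame_b[r1:(r1 + window - 1), c1:(c1 + window - 1)]
      b0 <- b - mean(b); sb <- sqrt(sum(b0^2))
      if (sb < 1e-12) next
      cc <- sum(a0 * b0) / (sa * sb)
      if (cc > best_cc) { best_cc <- cc; best <- c(dr, dc) }
    }
    ok <- is.finite(best_cc) && best_cc > 0.1
    res[[length(res) + 1]] <- c(r0, c0, best[2], best[1], as.numeric(ok))
  }
  m <- do.call(rbind, res)
  tibble::tibble(
    x_um = (m[, 2] + (window - 1) / 2) * px_um,
    y_um = (m[, 1] + (window - 1) / 2) * px_um,
    u_um_h = m[, 3] * px_um / dt_h,
    v_um_h = m[, 4] * px_um / dt_h,
    valid = m[, 5] > 0)
}
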