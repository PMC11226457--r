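#' Configuration for the per-pixel SAIM height fit
#'
#' @param h_min,h_max Height bounds in nm. The default 0--200 nm covers the
#'   40--140 nm display range of junctional proteins with margin.
#' @param restart_step_nm Spacing of the multi-start grid over `[h_min, h_max]`.
#' @param polarization Illumination polarization assumed by the forward
#'   model; azimuthally scanned TIRF-type illumination is treated as
#'   s-dominant, so `"TE"` is the default.
#' @param max_iter,ftol Levenberg--Marquardt iteration cap and relative
#'   decrease tolerance on the residual sum of squares.
#' @return A list of class `saim_fit_config`.
#' @export
saim_fit_config <- function(h_min = 0, h_max = 200, restart_step_nm = 10,
                            polarization = "TE", max_iter = 60, ftol = 1e-12) {
  stopifnot(h_min >= 0, h_max > h_min, restart_step_nm > 0)
  structure(list(h_min = h_min, h_max = h_max,
                 restart_step_nm = restart_step_nm,
                 polarization = polarization,
                 max_iter = max_iter, ftol = ftol),
            class = "saim_fit_config")
}

# Closed-form (A, B) given h: ordinary least squares of I ~ A F(h) + B with
# A clipped at 0 (amplitudes are physical intensities).
solve_linear_ab <- function(F_vals, intensities) {
  n <- length(F_vals)
  sf <- sum(F_vals); sf2 <- sum(F_vals^2)
  sy <- sum(intensities); sfy <- sum(F_vals * intensities)
  den <- n * sf2 - sf^2
  if (abs(den) < 1e-12) {
    A <- 0
  } else {
    A <- (n * sfy - sf * sy) / den
  }
  clipped <- FALSE
  if (A < 0) { A <- 0; clipped <- TRUE }
  B <- (sy - A * sf) / n
  rss <- sum((A * F_vals + B - intensities)^2)
  list(A = A, B = B, rss = rss, clipped = clipped)
}

# Damped Gauss-Newton (Levenberg-Marquardt) on (h, A, B) with analytic
# Jacobian; h kept inside [h_min, h_max] by clipping, A at >= 0.
lm_refine <- function(coefs, intensities, h0, A0, B0, config) {
  h <- h0; A <- A0; B <- B0
  Fh <- profile_eval(coefs, h)
  res <- A * Fh + B - intensities
  rss <- sum(res^2)
  lambda <- 1e-3
  for (iter in seq_len(config$max_iter)) {
    dF <- profile_deriv(coefs, h)
    j1 <- A * dF; j2 <- Fh
    # normal equations for J'J delta = -J'res with J = [j1 j2 1]
    g <- c(sum(j1 * res), sum(j2 * res), sum(res))
    H <- matrix(c(sum(j1 * j1), sum(j1 * j2), sum(j1),
                  sum(j1 * j2), sum(j2 * j2), sum(j2),
                  sum(j1),      sum(j2),      length(res)), 3, 3)
    improved <- FALSE
    for (k in 1:8) {
      Hd <- H + diag(lambda * diag(H) + 1e-12, 3)
      delta <- tryCatch(solve(Hd, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      h_new <- min(max(h + delta[1], config$h_min), config$h_max)
      A_new <- max(A + delta[2], 0)
      B_new <- B + delta[3]
      F_new <- profile_eval(coefs, h_new)
      res_new <- A_new * F_new + B_new - intensities
      rss_new <- sum(res_new^2)
      if (rss_new < rss) {
        h <- h_new; A <- A_new; B <- B_new
        Fh <- F_new; res <- res_new
        gain <- (rss - rss_new) / max(rss, 1e-300)
        rss <- rss_new
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        if (gain < config$ftol) {
          return(list(h = h, A = A, B = B, rss = rss, converged = TRUE))
        }
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) {
      return(list(h = h, A = A, B = B, rss = rss, converged = TRUE))
    }
  }
  list(h = h, A = A, B = B, rss = rss, converged = FALSE)
}

restart_grid <- function(config) {
  unique(c(seq(config$h_min, config$h_max, by = config$restart_step_nm),
           config$h_max))
}

#' Fit the standing-wave model to one pixel's angle-dependence curve
#'
#' Least-squares fit of measured intensities `I_j ~ A F_j(h) + B` over
#' `(h, A, B)` by multi-start Levenberg--Marquardt: from every start on the
#' restart grid, `(A, B)` are seeded by linear least squares and the full
#' three-parameter fit is refined; the restart with minimal residual sum of
#' squares wins, ties broken toward the lowest height.
#'
#' @param intensities Measured mean intensity at each sweep angle.
#' @param sweep An [angle_sweep()] of the same length.
#' @param stack A [layer_stack()].
#' @param config A [saim_fit_config()].
#' @return One-row tibble: `height_nm`, `amplitude`, `offset`, `residual_ss`,
#'   `converged`, `restart_index`, `amplitude_clipped`.
#' @export
fit_saim_pixel <- function(intensities, sweep = angle_sweep(),
                           stack = layer_stack(), config = saim_fit_config()) {
  stopifnot(length(intensities) == length(sweep))
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  coefs <- profile_coefs(sweep, stack, config$polarization)
  fit <- fit_pixel_internal(coefs, intensities, config)
  tibble::tibble(height_nm = fit$h, amplitude = fit$A, offset = fit$B,
                 residual_ss = fit$rss, converged = fit$converged,
                 restart_index = fit$restart_index,
                 amplitude_clipped = fit$clipped)
}

fit_pixel_internal <- function(coefs, intensities, config, starts = NULL) {
  # an all-constant curve carries no height information
  if (stats::sd(intensities) < 1e-12) {
    ab <- solve_linear_ab(profile_eval(coefs, config$h_min), intensities)
    return(list(h = config$h_min, A = ab$A, B = ab$B, rss = ab$rss,
                converged = FALSE, restart_index = NA_integer_,
                clipped = ab$clipped))
  }
  grid <- restart_grid(config)
  if (is.null(starts)) starts <- seq_along(grid)
  best <- NULL
  best_idx <- NA_integer_
  for (i in starts) {
    h0 <- grid[i]
    ab <- solve_linear_ab(profile_eval(coefs, h0), intensities)
    cand <- lm_refine(coefs, intensities, h0, ab$A, ab$B, config)
    if (is.null(best) ||
        cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 && cand$h < best$h)) {
      best <- cand
      best_idx <- i
    }
  }
  ab <- solve_linear_ab(profile_eval(coefs, best$h), intensities)
  best$clipped <- ab$clipped
  best$restart_index <- best_idx
  best
}

#' Fit a SAIM angle stack pixel-by-pixel
#'
#' Fits every masked pixel of an `angles x rows x cols` image stack
#' independently. To keep whole-field fits fast, the restart grid is scored
#' for all pixels at once through the profiled linear `(A, B)` subproblem
#' (the model is linear in amplitude and offset at fixed height) and the
#' Levenberg--Marquardt refinement then starts from each pixel's winning
#' restart.
#'
#' @param image_stack Numeric array `angles x rows x cols`; first dimension
#'   must match the sweep.
#' @param sweep,stack,config As for [fit_saim_pixel()].
#' @param mask Logical/numeric matrix `rows x cols`; nonzero pixels are
#'   fitted. Default: all pixels.
#' @return A list with `height_map` (matrix, nm; `NA` outside the mask) and
#'   `fits`, a tibble with one row per fitted pixel (`row`, `col`, plus the
#'   [fit_saim_pixel()] columns).
#' @export
fit_saim_stack <- function(image_stack, sweep = angle_sweep(),
                           stack = layer_stack(), mask = NULL,
                           config = saim_fit_config()) {
  d <- dim(image_stack)
  if (length(d) != 3 || d[1] != length(sweep)) {
    stop("image_stack must be angles x rows x cols with first dim matching the sweep",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!all(dim(mask) == d[2:3])) {
    stop("mask must match the spatial dimensions of the stack", call. = FALSE)
  }
  mask <- mask != 0
  idx <- which(mask)
  if (length(idx) == 0) stop("mask selects no pixels", call. = FALSE)

  coefs <- profile_coefs(sweep, stack, config$polarization)
  Y <- matrix(image_stack, nrow = d[1])[, idx, drop = FALSE]  # angles x npix

  # vectorized restart scoring: for each grid height, closed-form (A, B) per
  # pixel and the resulting RSS
  grid <- restart_grid(config)
  n <- d[1]
  sy <- colSums(Y)
  syy <- colSums(Y^2)
  best_rss <- rep(Inf, length(idx))
  best_start <- rep(1L, length(idx))
  for (i in seq_along(grid)) {
    Fh <- profile_eval(coefs, grid[i])
    sf <- sum(Fh); sf2 <- sum(Fh^2)
    sfy <- as.numeric(crossprod(Fh, Y))
    den <- n * sf2 - sf^2
    A <- if (abs(den) < 1e-12) rep(0, length(idx)) else (n * sfy - sf * sy) / den
    A[A < 0] <- 0
    B <- (sy - A * sf) / n
    rss <- syy + A^2 * sf2 + n * B^2 + 2 * A * B * sf - 2 * A * sfy - 2 * B * sy
    upd <- rss < best_rss
    best_rss[upd] <- rss[upd]
    best_start[upd] <- i
  }

  height_map <- matrix(NA_real_, d[2], d[3])
  rows <- integer(length(idx)); cols <- integer(length(idx))
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    fit <- fit_pixel_internal(coefs, Y[, k], config, starts = best_start[k])
    out[[k]] <- c(fit$h, fit$A, fit$B, fit$rss, as.numeric(fit$converged),
                  fit$restart_index, as.numeric(fit$clipped))
    height_map[idx[k]] <- fit$h
  }
  m <- do.call(rbind, out)
  rc <- arrayInd(idx, d[2:3])
  fits <- tibble::tibble(row = rc[, 1], col = rc[, 2],
                         height_nm = m[, 1], amplitude = m[, 2],
                         offset = m[, 3], residual_ss = m[, 4],
                         converged = m[, 5] > 0,
                         restart_index = as.integer(m[, 6]),
                         amplitude_clipped = m[, 7] > 0)
  list(height_map = height_map, fits = fits)
}

#' Summarize an ROI by its median fitted height (z-center)
#'
#' The representative axial position of a region of interest is the median
#' of the finite fitted per-pixel heights inside the mask (even-count median
#' is the mean of the two central values, the base-R convention).
#'
#' @param height_map Matrix of fitted heights (nm), `NA` where unfitted.
#' @param mask Logical/numeric matrix selecting the ROI; default whole map.
#' @param roi_id Label carried into the result.
#' @return One-row tibble: `roi_id`, `n_pixels`, `n_nonfinite`, `z_center_nm`.
#' @export
roi_zcenter <- function(height_map, mask = NULL, roi_id = "roi1") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(height_map), ncol(height_map))
  stopifnot(all(dim(mask) == dim(height_map)))
  vals <- height_map[mask != 0]
  finite <- vals[is.finite(vals)]
  if (length(finite) == 0) {
    stop("ROI contains no finite fitted heights", call. = FALSE)
  }
  tibble::tibble(roi_id = roi_id,
                 n_pixels = length(finite),
                 n_nonfinite = length(vals) - length(finite),
                 z_center_nm = stats::median(finite))
}

#' Render a topographic height map
#'
#' Hue-encodes fitted heights over a fixed color range (defaults to the
#' 40--140 nm display window used for junctional proteins); heights outside
#' the range are clamped to the end colors. The rendering is derived output;
#' the height map itself is the primary data.
#'
#' @param height_map Matrix of heights in nm.
#' @param color_range Length-2 numeric, `c(min, max)` of the color scale.
#' @return A ggplot object.
#' @export
plot_height_map <- function(height_map, color_range = c(40, 140)) {
  stopifnot(length(color_range) == 2, color_range[1] < color_range[2])
  df <- tidyr::expand_grid(row = seq_len(nrow(height_map)),
                           col = seq_len(ncol(height_map)))
  df$height_nm <- pmin(pmax(height_map[cbind(df$row, df$col)],
                            color_range[1]), color_range[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = grDevices::rainbow(64, end = 0.7),
                                  limits = color_range, name = "z (nm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
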