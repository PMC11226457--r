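#' Seeded synthetic-data generators
#'
#' Each generator emulates one input kind of the pipeline with the
#' statistical structure its analysis assumes, returns the data together
#' with a machine-readable `truth` list of every ground-truth parameter,
#' and is bit-reproducible for a fixed seed. A top-level seed can be split
#' into independent per-generator streams with [split_seed()].
#'
#' @name simulators
NULL

#' Split one top-level seed into per-generator streams
#'
#' Deterministic integer hashing of `(seed, index)`; streams for different
#' indices are decorrelated and all results stay within the 32-bit integer
#' range.
#'
#' @param seed Integer top-level seed.
#' @param n Number of streams.
#' @return Integer vector of `n` derived seeds.
#' @export
split_seed <- function(seed, n) {
  vapply(seq_len(n), function(i) {
    x <- (as.double(seed) * 2654435761 + i * 40503) %% 2147483647
    as.integer(x)
  }, integer(1))
}

#' Simulate a SAIM angle-scan image stack
#'
#' Per-pixel forward model `A * F(h) + B` with multiplicative Gaussian
#' noise of fractional SD `noise_frac`, over the standard 14-angle sweep.
#'
#' @param height_nm Ground-truth height: a scalar (uniform field) or a
#'   matrix of per-pixel heights.
#' @param nrow,ncol Field size when `height_nm` is scalar.
#' @param sweep,stack Optics, as in [excitation_profile()].
#' @param amplitude,offset Scale `A` and background `B` in camera units.
#' @param noise_frac Fractional multiplicative noise SD (e.g. 0.02).
#' @param seed Integer seed.
#' @return List: `image_stack` (angles x rows x cols), `truth`.
#' @export
sim_saim_stack <- function(height_nm, nrow = 64, ncol = 64,
                           sweep = angle_sweep(), stack = layer_stack(),
                           amplitude = 500, offset = 50,
                           noise_frac = 0.02, seed = 1) {
  stopifnot(noise_frac >= 0)
  if (is.matrix(height_nm)) {
    hm <- height_nm
  } else {
    hm <- matrix(height_nm, nrow, ncol)
  }
  heights <- sort(unique(as.vector(hm)))
  profiles <- vapply(heights, excitation_profile, numeric(length(sweep)),
                     sweep = sweep, stack = stack)
  mat <- matrix(NA_real_, length(sweep), length(hm))
  for (j in seq_along(heights)) {
    sel <- which(hm == heights[j])
    mat[, sel] <- amplitude * profiles[, j] + offset
  }
  withr::with_seed(seed, {
    if (noise_frac > 0) {
      mat <- mat * (1 + stats::rnorm(length(mat), sd = noise_frac))
    }
  })
  arr <- array(mat, c(length(sweep), nrow(hm), ncol(hm)))
  list(image_stack = arr,
       truth = list(height_nm = hm, amplitude = amplitude, offset = offset,
                    noise_frac = noise_frac, seed = seed,
                    angles_deg = as.numeric(sweep),
                    wavelength_nm = stack$wavelength_nm,
                    oxide_thickness_nm = stack$oxide_thickness_nm))
}

# smooth force-dependent tether baseline: worm-like-chain-like saturating rise
tether_baseline <- function(force_pN, scale_nm = 60, f_half_pN = 2) {
  scale_nm * force_pN / (force_pN + f_half_pN)
}

#' Simulate a magnetic-tweezer force-ramp trace
#'
#' Bead height = smooth force-dependent tether baseline + planted steps at
#' the event forces + Gaussian noise, over a linear force ramp.
#'
#' @param ramp A [force_ramp()].
#' @param events Data frame with columns `force_pN`, `delta_h_nm`; the
#'   planted dissociation/unfolding steps (may be empty).
#' @param noise_nm Gaussian height noise SD.
#' @param baseline_scale_nm Amplitude of the saturating baseline.
#' @param seed Integer seed.
#' @param detector_window Used only to flag events planted closer together
#'   than one detection window.
#' @return List: `trace` tibble (`time_s`, `force_pN`, `height_nm`),
#'   `truth`.
#' @export
sim_tweezer_trace <- function(ramp = force_ramp(), events = NULL,
                              noise_nm = 5, baseline_scale_nm = 60,
                              seed = 1, detector_window = 30) {
  if (is.null(events)) {
    events <- tibble::tibble(force_pN = numeric(), delta_h_nm = numeric())
  }
  stopifnot(all(events$force_pN > ramp$f_start),
            all(events$force_pN < ramp$f_end))
  tt <- seq(0, (ramp$f_end - ramp$f_start) / ramp$load_rate_pN_s,
            by = ramp$sample_dt_s)
  ff <- ramp$f_start + ramp$load_rate_pN_s * tt
  h <- tether_baseline(ff, baseline_scale_nm)
  for (i in seq_len(nrow(events))) {
    h <- h + events$delta_h_nm[i] * (ff >= events$force_pN[i])
  }
  if (nrow(events) > 1) {
    gaps <- diff(sort(events$force_pN)) / ramp$load_rate_pN_s / ramp$sample_dt_s
    if (any(gaps < detector_window)) {
      warning("planted events closer than one detector window")
    }
  }
  withr::with_seed(seed, {
    if (noise_nm > 0) h <- h + stats::rnorm(length(h), sd = noise_nm)
  })
  list(trace = tibble::tibble(time_s = tt, force_pN = ff, height_nm = h),
       truth = list(events = events, noise_nm = noise_nm,
                    baseline_scale_nm = baseline_scale_nm, seed = seed))
}

#' Simulate a raw three-channel FRAP trace
#'
#' Builds raw bleached-ROI, reference-ROI and background series such that
#' double normalization followed by full-scale calibration recovers the
#' underlying recovery model `p (1 - exp(-k t))`: the bleached-ROI
#' concentration drops to `1 - bleach_depth` at the bleach frame and
#' recovers by the fraction `p` of what was bleached; both ROIs decay with
#' acquisition photobleaching at `photobleach_rate` per frame.
#'
#' @param p Mobile fraction (plateau of the full-scale curve), in `[0, 1]`.
#' @param k Recovery rate constant, 1/s.
#' @param n_frames,dt_s Number of frames and frame interval (90 at 1 s).
#' @param bleach_index Pre-bleach frame count (bleach after frame 4).
#' @param bleach_depth Fraction of bleached-ROI signal removed by the
#'   bleach, in `(0, 1]`.
#' @param photobleach_rate Acquisition photobleaching per frame (e.g.
#'   0.002 = 0.2\% per frame).
#' @param background_level Constant background in camera units.
#' @param i0 Pre-bleach signal above background, camera units.
#' @param noise_sd Additive Gaussian noise SD in full-scale (normalized)
#'   units; applied to the raw channels scaled accordingly.
#' @param seed Integer seed.
#' @return List: `trace` tibble (`time_s`, `i_frap`, `i_ref`, `i_back`),
#'   `truth`.
#' @export
sim_frap_trace <- function(p = 0.331, k = log(2) / 29.02, n_frames = 90,
                           dt_s = 1, bleach_index = 4, bleach_depth = 0.8,
                           photobleach_rate = 0.002, background_level = 100,
                           i0 = 1000, noise_sd = 0.05, seed = 1) {
  stopifnot(p >= 0, p <= 1, k > 0, bleach_depth > 0, bleach_depth <= 1,
            noise_sd >= 0)
  tt <- (seq_len(n_frames) - 1) * dt_s
  t_bleach <- tt[bleach_index + 1]
  tau <- pmax(tt - t_bleach, 0)
  recovery <- ifelse(tt < t_bleach, 1,
                     (1 - bleach_depth) + bleach_depth * p * (1 - exp(-k * tau)))
  acq <- (1 - photobleach_rate)^(seq_len(n_frames) - 1)
  i_ref_clean <- i0 * acq
  i_frap_clean <- i0 * recovery * acq
  withr::with_seed(seed, {
    noise_raw <- noise_sd * i0 * bleach_depth
    nse <- stats::rnorm(n_frames, sd = noise_raw)
    # the bleach (floor) frame is the anchor of the full-scale calibration;
    # it is part of the normalization scaffold the generator guarantees
    # invertible (unbiased recovery of p), so it carries no measurement
    # noise -- see the methods vignette for what this idealizes away
    nse[bleach_index + 1] <- 0
    i_frap <- i_frap_clean + nse
    i_ref <- i_ref_clean + stats::rnorm(n_frames, sd = noise_raw / 4)
    i_back <- background_level + stats::rnorm(n_frames, sd = noise_raw / 10)
  })
  list(trace = tibble::tibble(time_s = tt,
                              i_frap = i_frap + background_level,
                              i_ref = i_ref + background_level,
                              i_back = i_back),
       truth = list(p = p, k = k, half_life_s = log(2) / k,
                    bleach_index = bleach_index, bleach_depth = bleach_depth,
                    photobleach_rate = photobleach_rate, noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate an ablation edge track
#'
#' Symmetric edge motion along the separation axis: inter-edge distance
#' grows linearly at `ballistic_rate` for the first two post-ablation
#' frames, then relaxes exponentially toward a plateau with time constant
#' `saturation_tau`. By construction the noiseless first-2-s secant equals
#' `ballistic_rate`.
#'
#' @param ballistic_rate Initial recoil rate, um/s.
#' @param saturation_tau Relaxation time constant, s.
#' @param d0 Pre-ablation inter-edge distance, um.
#' @param frame_dt_s Frame interval (2 s).
#' @param n_pre,n_post Pre-ablation frames (3: -6, -4, -2 s) and
#'   post-ablation frames beyond t = 0 (15: 2 ... 30 s).
#' @param noise_um Positional Gaussian noise SD per coordinate.
#' @param angle_deg Orientation of the separation axis in the image plane.
#' @param seed Integer seed.
#' @return List: `track` tibble (`time_s`, `e1x_um`, `e1y_um`, `e2x_um`,
#'   `e2y_um`, attribute `ablation_time_s = 0`), `truth`.
#' @export
sim_recoil_track <- function(ballistic_rate = 1.77, saturation_tau = 10,
                             d0 = 1, frame_dt_s = 2, n_pre = 3, n_post = 15,
                             noise_um = 0, angle_deg = 0, seed = 1) {
  stopifnot(ballistic_rate >= 0, saturation_tau > 0, noise_um >= 0)
  tt <- seq(-n_pre * frame_dt_s, n_post * frame_dt_s, by = frame_dt_s)
  t_ball <- 2 * frame_dt_s
  d_ball_end <- d0 + ballistic_rate * t_ball
  d_plateau <- d_ball_end + ballistic_rate * saturation_tau / 2
  dist <- ifelse(tt < 0, d0,
                 ifelse(tt <= t_ball, d0 + ballistic_rate * tt,
                        d_plateau - (d_plateau - d_ball_end) *
                          exp(-(tt - t_ball) / saturation_tau)))
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  withr::with_seed(seed, {
    nse <- if (noise_um > 0) {
      matrix(stats::rnorm(4 * length(tt), sd = noise_um), ncol = 4)
    } else matrix(0, length(tt), 4)
  })
  track <- tibble::tibble(
    time_s = tt,
    e1x_um = -dist / 2 * ux + nse[, 1], e1y_um = -dist / 2 * uy + nse[, 2],
    e2x_um = dist / 2 * ux + nse[, 3], e2y_um = dist / 2 * uy + nse[, 4])
  attr(track, "ablation_time_s") <- 0
  list(track = track,
       truth = list(ballistic_rate = ballistic_rate,
                    saturation_tau = saturation_tau, d0 = d0,
                    noise_um = noise_um, angle_deg = angle_deg, seed = seed))
}

#' Simulate migration velocity fields
#'
#' Vector angles are von Mises about `mean_angle_deg` with concentration
#' `kappa`; speeds are Gaussian truncated at zero, with a `static_fraction`
#' of vectors drawn uniformly below the standard 10 um/h noise filter.
#'
#' @param mean_angle_deg Ground-truth flow direction (0 = wound normal).
#' @param kappa von Mises concentration (0 = uniform angles).
#' @param speed_mean,speed_sd Speed distribution, um/h.
#' @param static_fraction Fraction of sub-threshold (noise) vectors.
#' @param n_x,n_y Grid size per frame.
#' @param n_frames Number of frames.
#' @param grid_um Grid spacing, um.
#' @param seed Integer seed.
#' @return List: `fields` tibble (`frame`, `x_um`, `y_um`, `u_um_h`,
#'   `v_um_h`, `valid`), `truth`.
#' @export
sim_velocity_fields <- function(mean_angle_deg = 0, kappa = 4,
                                speed_mean = 25, speed_sd = 8,
                                static_fraction = 0.2, n_x = 20, n_y = 20,
                                n_frames = 5, grid_um = 16, seed = 1) {
  stopifnot(kappa >= 0, speed_mean > 0, static_fraction >= 0,
            static_fraction < 1)
  n <- n_x * n_y * n_frames
  withr::with_seed(seed, {
    ang <- rvonmises(n, mean_angle_deg * pi / 180, kappa)
    speed <- pmax(stats::rnorm(n, speed_mean, speed_sd), 0)
    static <- stats::runif(n) < static_fraction
    speed[static] <- stats::runif(sum(static), 0, 9.999)
  })
  grid <- tidyr::expand_grid(frame = seq_len(n_frames),
                             y_um = (seq_len(n_y) - 1) * grid_um,
                             x_um = (seq_len(n_x) - 1) * grid_um)
  fields <- tibble::tibble(frame = grid$frame, x_um = grid$x_um,
                           y_um = grid$y_um,
                           u_um_h = speed * cos(ang),
                           v_um_h = speed * sin(ang),
                           valid = TRUE)
  list(fields = fields,
       truth = list(mean_angle_deg = mean_angle_deg, kappa = kappa,
                    speed_mean = speed_mean, speed_sd = speed_sd,
                    static_fraction = static_fraction, seed = seed))
}

# von Mises sampler (Best & Fisher rejection algorithm); kappa = 0 falls
# back to uniform angles
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}
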