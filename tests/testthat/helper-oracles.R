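# Independent oracles, kept deliberately separate from the package's own
# implementations: a characteristic-matrix (Born-Wolf) thin-film solver, a
# bisection inversion of the worm-like-chain force law, and an exhaustive
# grid search for the per-pixel height fit.

# 2x2 characteristic-matrix reflection coefficient of the
# medium/oxide/silicon stack (e^{-i omega t} convention)
oracle_reflectance <- function(theta_deg, stack, pol = "TE") {
  th1 <- theta_deg * pi / 180
  n <- c(stack$n_medium, stack$n_oxide, stack$n_silicon)
  ct <- sapply(n, function(ni) sqrt(1 - (n[1] * sin(th1) / ni)^2 + 0i))
  q <- if (pol == "TE") n * ct else ct / n
  beta <- 2 * pi * n[2] * stack$oxide_thickness_nm * ct[2] / stack$wavelength_nm
  M <- matrix(c(cos(beta), -1i * sin(beta) * q[2],
                -1i * sin(beta) / q[2], cos(beta)), 2, 2)
  num <- q[1] * (M[1, 1] + M[1, 2] * q[3]) - (M[2, 1] + M[2, 2] * q[3])
  den <- q[1] * (M[1, 1] + M[1, 2] * q[3]) + (M[2, 1] + M[2, 2] * q[3])
  num / den
}

# bisection root of the Marko-Siggia force law F(z) = f over z = x/L
oracle_wlc_extension <- function(force_pN, contour_nm, persistence_nm = 0.8,
                                 kT = 4.28, tol = 1e-10) {
  if (force_pN == 0) return(0)
  fz <- function(z) (kT / persistence_nm) * (1 / (4 * (1 - z)^2) - 0.25 + z)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fz(mid) < force_pN) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 * contour_nm
}

# exhaustive grid search over h with the (A, B) linear subproblem solved
# exactly at every grid point
oracle_grid_fit <- function(intensities, sweep, stack, h_min = 0, h_max = 200,
                            step = 0.01) {
  hs <- seq(h_min, h_max, by = step)
  best <- list(rss = Inf)
  for (h in hs) {
    F_vals <- excitation_profile(h, sweep, stack)
    X <- cbind(F_vals, 1)
    cf <- solve(crossprod(X), crossprod(X, intensities))
    A <- max(cf[1], 0)
    B <- if (A == cf[1]) cf[2] else mean(intensities) - A * mean(F_vals)
    rss <- sum((A * F_vals + B - intensities)^2)
    if (rss < best$rss) best <- list(h = h, A = A, B = B, rss = rss)
  }
  best
}
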