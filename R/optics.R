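#' Optical description of a SAIM imaging substrate
#'
#' Scanning-angle interference microscopy (SAIM) places the sample above a
#' silicon mirror carrying a thin thermal-oxide spacer. A fluorophore at
#' height `h` above the oxide surface is excited by the standing wave formed
#' by the direct and mirror-reflected illumination beams; the angular
#' modulation of that standing wave encodes `h`. `layer_stack()` bundles the
#' optical constants of the medium/oxide/silicon stack needed by the forward
#' model.
#'
#' The imaginary part of `n_silicon` is negative (absorbing medium under the
#' `exp(+i k z)` propagation convention used throughout); a positive
#' imaginary part is flipped with a warning so both sign conventions are
#' accepted on input.
#'
#' @param wavelength_nm Excitation wavelength in nm.
#' @param oxide_thickness_nm SiO2 spacer thickness in nm (~500 nm for the
#'   substrates modelled here).
#' @param n_medium Real refractive index of the aqueous medium.
#' @param n_oxide Real refractive index of the thermal oxide.
#' @param n_silicon Complex refractive index of silicon at `wavelength_nm`.
#'   Defaults to 4.37 - 0.08i, a textbook value at 488 nm; use
#'   ~4.05 - 0.04i at 561 nm.
#' @return An object of class `layer_stack`.
#' @examples
#' layer_stack()
#' layer_stack(wavelength_nm = 561, n_silicon = complex(real = 4.05, imaginary = -0.04))
#' @export
layer_stack <- function(wavelength_nm = 488,
                        oxide_thickness_nm = 500,
                        n_medium = 1.33,
                        n_oxide = 1.463,
                        n_silicon = complex(real = 4.37, imaginary = -0.08)) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1, wavelength_nm > 0)
  stopifnot(is.numeric(oxide_thickness_nm), length(oxide_thickness_nm) == 1,
            oxide_thickness_nm >= 0)
  n_silicon <- as.complex(n_silicon)
  if (Re(n_medium) < 1 || Re(n_oxide) < 1 || Re(n_silicon) < 1) {
    stop("real parts of all refractive indices must be >= 1", call. = FALSE)
  }
  if (Im(n_silicon) > 0) {
    warning("flipping sign of Im(n_silicon) to the absorbing convention (negative)")
    n_silicon <- Conj(n_silicon)
  }
  structure(
    list(wavelength_nm = wavelength_nm,
         oxide_thickness_nm = oxide_thickness_nm,
         n_medium = as.numeric(n_medium),
         n_oxide = as.numeric(n_oxide),
         n_silicon = n_silicon),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack>  lambda =", x$wavelength_nm, "nm, oxide =",
      x$oxide_thickness_nm, "nm\n")
  cat("  n_medium =", x$n_medium, " n_oxide =", x$n_oxide,
      " n_silicon =", format(x$n_silicon), "\n")
  invisible(x)
}

#' Illumination angle sweep
#'
#' The sweep lists the incidence angles (in the sample medium) at which
#' frames of a SAIM stack were acquired. The default reproduces the standard
#' acquisition: 14 angles from 0 (normal) to 52 degrees in 4-degree steps.
#'
#' @param angles_deg Strictly increasing vector of angles in `[0, 90)`
#'   degrees, length >= 3 (the per-pixel fit has three free parameters).
#' @return A numeric vector of class `angle_sweep`.
#' @export
angle_sweep <- function(angles_deg = seq(0, 52, by = 4)) {
  stopifnot(is.numeric(angles_deg), length(angles_deg) >= 3)
  if (any(!is.finite(angles_deg)) || any(angles_deg < 0) || any(angles_deg >= 90)) {
    stop("angles must be finite and in [0, 90) degrees", call. = FALSE)
  }
  if (any(diff(angles_deg) <= 0)) {
    stop("angles must be strictly increasing", call. = FALSE)
  }
  structure(as.numeric(angles_deg), class = "angle_sweep")
}

# cos(theta) in layer with index n, for incidence at theta1 in the medium.
# Principal square root keeps Im(n*cos) >= 0 for absorbing layers, i.e. a
# transmitted wave that decays into the substrate.
layer_cos <- function(theta1_rad, n1, n) {
  s <- n1 * sin(theta1_rad) / n
  sqrt(1 - s * s + 0i)
}

#' Complex reflection coefficient of the medium/oxide/silicon mirror
#'
#' Amplitude reflection coefficient of the imaging substrate seen from the
#' sample medium, from standard single-film (Airy) interference between the
#' medium/oxide and oxide/silicon interfaces:
#' \deqn{r = \frac{r_{12} + r_{23} e^{2 i \beta}}{1 + r_{12} r_{23} e^{2 i \beta}},
#'   \qquad \beta = \frac{2 \pi}{\lambda} n_{ox} d \cos\theta_{ox}.}
#'
#' @param theta_deg Incidence angle(s) in the medium, degrees, in `[0, 90)`.
#' @param stack A [layer_stack()].
#' @param polarization `"TE"` (s, default), `"TM"` (p), or `"average"`
#'   (mean of the TE and TM coefficients).
#' @return Complex vector of reflection coefficients, `|r| <= 1`.
#' @examples
#' mirror_reflectance(0, layer_stack())
#' @export
mirror_reflectance <- function(theta_deg, stack = layer_stack(),
                               polarization = c("TE", "TM", "average")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "layer_stack"))
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) || any(theta_deg >= 90)) {
    stop("incidence angle must be finite and in [0, 90) degrees", call. = FALSE)
  }
  if (polarization == "average") {
    return((mirror_reflectance(theta_deg, stack, "TE") +
              mirror_reflectance(theta_deg, stack, "TM")) / 2)
  }
  th1 <- theta_deg * pi / 180
  n1 <- stack$n_medium
  n2 <- stack$n_oxide
  n3 <- stack$n_silicon
  c1 <- cos(th1) + 0i
  c2 <- layer_cos(th1, n1, n2)
  # oxide is denser than the medium, so no TIR at the first interface; guard
  # anyway for exotic index overrides
  if (any(abs(Im(c2)) > 1e-9)) {
    stop("angle beyond the total-internal-reflection limit of the oxide layer",
         call. = FALSE)
  }
  c3 <- layer_cos(th1, n1, n3)
  if (polarization == "TE") {
    r12 <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
    r23 <- (n2 * c2 - n3 * c3) / (n2 * c2 + n3 * c3)
  } else {
    r12 <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
    r23 <- (n3 * c2 - n2 * c3) / (n3 * c2 + n2 * c3)
  }
  beta <- 2 * pi * n2 * stack$oxide_thickness_nm * c2 / stack$wavelength_nm
  ph <- exp(2i * beta)
  (r12 + r23 * ph) / (1 + r12 * r23 * ph)
}

#' Standing-wave excitation profile of a fluorophore above the mirror
#'
#' Unit-amplitude excitation intensity at each sweep angle for a fluorophore
#' at height `height_nm` above the oxide surface:
#' \deqn{F_j = |1 + r(\theta_j) e^{i \phi_j}|^2, \qquad
#'   \phi_j = \frac{4 \pi n_m h \cos\theta_j}{\lambda}.}
#' Values lie in `[0, 4]`.
#'
#' @param height_nm Fluorophore height above the oxide surface, nm, >= 0.
#' @param sweep An [angle_sweep()].
#' @param stack A [layer_stack()].
#' @param polarization Passed to [mirror_reflectance()].
#' @return Numeric vector, one intensity per sweep angle.
#' @examples
#' excitation_profile(100, angle_sweep(), layer_stack())
#' @export
excitation_profile <- function(height_nm, sweep = angle_sweep(),
                               stack = layer_stack(), polarization = "TE") {
  stopifnot(length(sweep) >= 1)
  if (!is.finite(height_nm) || height_nm < 0) {
    stop("height_nm must be finite and >= 0", call. = FALSE)
  }
  r <- mirror_reflectance(as.numeric(sweep), stack, polarization)
  th <- as.numeric(sweep) * pi / 180
  phi <- 4 * pi * stack$n_medium * height_nm * cos(th) / stack$wavelength_nm
  Mod(1 + r * exp(1i * phi))^2
}

# Precompute the angle-dependent pieces of F(h) = a + b cos(c h) + d sin(c h)
# so fitting loops touch only real arithmetic.
profile_coefs <- function(sweep, stack, polarization = "TE") {
  r <- mirror_reflectance(as.numeric(sweep), stack, polarization)
  th <- as.numeric(sweep) * pi / 180
  list(a = 1 + Mod(r)^2,
       b = 2 * Re(r),
       d = -2 * Im(r),
       c = 4 * pi * stack$n_medium * cos(th) / stack$wavelength_nm)
}

profile_eval <- function(coefs, h) {
  coefs$a + coefs$b * cos(coefs$c * h) + coefs$d * sin(coefs$c * h)
}

profile_deriv <- function(coefs, h) {
  coefs$c * (-coefs$b * sin(coefs$c * h) + coefs$d * cos(coefs$c * h))
}
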