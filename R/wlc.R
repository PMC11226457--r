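#' Worm-like-chain parameters for an unstructured polypeptide
#'
#' The force--extension behaviour of the released polypeptide is modelled by
#' the Marko--Siggia interpolation of the worm-like chain. Defaults: bending
#' persistence length ~0.8 nm (unfolded polypeptide), contour length
#' 0.38 nm per residue, and thermal energy at 37 degrees C
#' (kT = 4.28 pN nm).
#'
#' @param persistence_nm Bending persistence length, nm.
#' @param contour_per_residue_nm Contour length per amino acid, nm.
#' @param kT_pN_nm Thermal energy, pN nm.
#' @return A list of class `wlc_params`.
#' @export
wlc_params <- function(persistence_nm = 0.8, contour_per_residue_nm = 0.38,
                       kT_pN_nm = 4.28) {
  stopifnot(persistence_nm > 0, contour_per_residue_nm > 0, kT_pN_nm > 0)
  structure(list(persistence_nm = persistence_nm,
                 contour_per_residue_nm = contour_per_residue_nm,
                 kT_pN_nm = kT_pN_nm),
            class = "wlc_params")
}

#' Marko--Siggia worm-like-chain force law
#'
#' Force at fractional extension `z = x / L`:
#' \deqn{F(z) = \frac{kT}{L_p}\left[\frac{1}{4 (1 - z)^2} - \frac14 + z\right].}
#'
#' @param extension_nm Extension x, `0 <= x < contour_nm`.
#' @param contour_nm Contour length L, nm.
#' @param params A [wlc_params()].
#' @return Force in pN.
#' @export
wlc_force <- function(extension_nm, contour_nm, params = wlc_params()) {
  stopifnot(contour_nm > 0)
  z <- extension_nm / contour_nm
  if (any(z < 0) || any(z >= 1)) {
    stop("extension must lie in [0, contour)", call. = FALSE)
  }
  (params$kT_pN_nm / params$persistence_nm) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Worm-like-chain extension at a given force
#'
#' Numerically inverts the Marko--Siggia force law (monotone in extension),
#' converged to `|F(x) - force| < 1e-6` pN.
#'
#' @param force_pN Applied force, pN, >= 0 (vectorized).
#' @param contour_nm Contour length of the stretched segment, nm.
#' @param params A [wlc_params()].
#' @return Extension in nm, in `[0, contour_nm)`.
#' @examples
#' wlc_extension(16, 182 * 0.38)
#' @export
wlc_extension <- function(force_pN, contour_nm, params = wlc_params()) {
  if (any(!is.finite(force_pN)) || !is.finite(contour_nm)) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(force_pN < 0) || contour_nm <= 0) {
    stop("force must be >= 0 and contour > 0", call. = FALSE)
  }
  vapply(force_pN, function(f) {
    if (f == 0) return(0)
    g <- function(z) wlc_force(z * contour_nm, contour_nm, params) - f
    root <- stats::uniroot(g, c(0, 1 - 1e-9), tol = 1e-12)$root
    root * contour_nm
  }, numeric(1))
}

#' Single-molecule detector construct model
#'
#' Residue accounting for the looped avi--VBS--FH1--VD1--I27(x2)--spy
#' detector. On dissociation of the VBS--VD1 complex the FH1 spacer loop,
#' its flanking GGGSG linkers and the VBS segment (no longer a docked helix)
#' become load-bearing disordered chain; each released segment's worm-like
#' chain extension is credited minus the span the folded state already
#' contributed. Each of the two VD1 helix-bundle subunits releases
#' `subunit_residues` of contour on unfolding.
#'
#' @param loop_residues Residues of the FH1 spacer loop (182).
#' @param flexible_linker_residues Additional residues released with the
#'   loop: two GGGSG spacers plus the ~30-residue VBS segment (default 40).
#' @param subunit_residues Residues released per VD1 subunit unfolding
#'   (default 126 = 252-residue VD1 split over its two subunits; taken as
#'   configuration, the exact count is construct-specific).
#' @param n_subunits Number of VD1 subunits (2).
#' @param folded_span_nm Extension already credited to each folded element
#'   (complex span or folded bundle diameter), subtracted per release.
#' @return A list of class `construct_model`.
#' @export
construct_model <- function(loop_residues = 182, flexible_linker_residues = 40,
                            subunit_residues = 126, n_subunits = 2,
                            folded_span_nm = 4) {
  stopifnot(loop_residues > 0, flexible_linker_residues >= 0,
            subunit_residues > 0, n_subunits == 2, folded_span_nm >= 0)
  structure(list(loop_residues = loop_residues,
                 flexible_linker_residues = flexible_linker_residues,
                 subunit_residues = subunit_residues,
                 n_subunits = n_subunits,
                 folded_span_nm = folded_span_nm),
            class = "construct_model")
}

release_contours <- function(scenario, construct, params) {
  loop_nm <- (construct$loop_residues + construct$flexible_linker_residues) *
    params$contour_per_residue_nm
  sub_nm <- construct$subunit_residues * params$contour_per_residue_nm
  switch(scenario,
         unloop_only = loop_nm,
         unloop_partial_unfold = c(loop_nm, sub_nm),
         unloop_full_unfold = c(loop_nm, rep(sub_nm, construct$n_subunits)),
         subunit_unfold = sub_nm,
         stop("unknown scenario: ", scenario, call. = FALSE))
}

#' Predicted bead-height step for a dissociation/unfolding scenario
#'
#' The stepwise bead-height change is the sum, over every segment released
#' in the scenario, of its worm-like-chain extension at the given force
#' minus the folded span already spanned before release. Scenarios:
#' `unloop_only` (VBS--VD1 dissociation releasing the FH1 loop),
#' `unloop_partial_unfold` (plus one VD1 subunit), `unloop_full_unfold`
#' (plus both subunits), and `subunit_unfold` (one subunit alone, the
#' ~35 nm step seen without a loop).
#'
#' @param scenario One of the four scenario labels (vectorized).
#' @param force_pN Force at the transition, pN, in `(0, 60]`.
#' @param construct A [construct_model()].
#' @param params A [wlc_params()].
#' @return Predicted step size in nm (clipped at 0).
#' @examples
#' predicted_step("unloop_only", c(7, 16))
#' @export
predicted_step <- function(scenario, force_pN, construct = construct_model(),
                           params = wlc_params()) {
  stopifnot(all(force_pN > 0), all(force_pN <= 60))
  if (length(scenario) > 1 && length(force_pN) == 1) {
    force_pN <- rep(force_pN, length(scenario))
  }
  if (length(scenario) == 1 && length(force_pN) > 1) {
    scenario <- rep(scenario, length(force_pN))
  }
  mapply(function(sc, f) {
    L <- release_contours(sc, construct, params)
    dh <- sum(vapply(L, function(li) wlc_extension(f, li, params), numeric(1)) -
                construct$folded_span_nm)
    max(dh, 0)
  }, scenario, force_pN, USE.NAMES = FALSE)
}

#' Absolute force uncertainty of the magnetic-tweezer measurement
#'
#' Bead-size variation and tether attachment geometry give a relative force
#' uncertainty of 20%; the absolute uncertainty is `0.20 * force`.
#'
#' @param force_pN Measured force, pN, >= 0.
#' @return Absolute uncertainty in pN.
#' @export
force_error <- function(force_pN) {
  stopifnot(all(force_pN >= 0))
  0.20 * force_pN
}
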