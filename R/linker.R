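# Linker geometry: maps the rigidity and length of the alpha-helical fusion
# linker to the orientation of the mEGFP excitation dipole relative to the
# NPC axis. Each residue added to a rigid alpha-helical linker twists the
# fluorophore about the helix axis by a fixed angle (103 degrees by default);
# a flexible linker decouples the fluorophore, which then wobbles
# isotropically whatever its length.

#' Specification of the Nup-mEGFP fusion linker
#'
#' @param kind `"rigid"` (continuous alpha helix; orientation is a
#'   deterministic function of length) or `"flexible"` (dipole orientation
#'   decoupled from the host protein).
#' @param length_residues Number of linker residues added relative to the
#'   reference construct (integer >= 0).
#' @param rotation_per_residue_deg Twist of the fluorophore about the helix
#'   axis per added residue, degrees in (0, 360). The default, 103, is the
#'   per-residue twist of the sensor's helical linker.
#' @return An object of class `linker_spec`.
#' @export
linker_spec <- function(kind = c("rigid", "flexible"), length_residues = 0,
                        rotation_per_residue_deg = 103) {
  kind <- match.arg(kind)
  stopifnot(length_residues >= 0, length_residues == round(length_residues),
            rotation_per_residue_deg > 0, rotation_per_residue_deg < 360)
  structure(
    list(kind = kind,
         length_residues = as.integer(length_residues),
         rotation_per_residue_deg = rotation_per_residue_deg),
    class = "linker_spec")
}

#' Attachment geometry of the fluorophore on the helix
#'
#' Fixed angles relating the linker helix and the fluorophore dipole to the
#' NPC (z) axis: the helix axis polar angle `alpha`, the fixed angle `beta`
#' between the dipole and the helix axis, and the rotation phase of the
#' dipole about the helix axis at linker length zero. The helix azimuth is
#' fixed at zero without loss of generality because the excitation fields
#' are azimuth-averaged.
#'
#' @param helix_axis_polar_deg Angle of the helix axis from z, `[0, 180]`.
#' @param dipole_tilt_deg Angle between dipole and helix axis, `[0, 180]`.
#' @param phase_deg Dipole rotation about the helix axis at length zero.
#' @return An object of class `attachment_geometry`.
#' @export
attachment_geometry <- function(helix_axis_polar_deg = 45,
                                dipole_tilt_deg = 60, phase_deg = 0) {
  stopifnot(helix_axis_polar_deg >= 0, helix_axis_polar_deg <= 180,
            dipole_tilt_deg >= 0, dipole_tilt_deg <= 180)
  structure(
    list(helix_axis_polar_deg = helix_axis_polar_deg,
         dipole_tilt_deg = dipole_tilt_deg,
         phase_deg = phase_deg),
    class = "attachment_geometry")
}

#' Rotation of the dipole about the helix axis for a given linker
#'
#' For a rigid linker the fluorophore is rotated about the helix axis by
#' `length_residues * rotation_per_residue_deg` (mod 360), so two constructs
#' differing by one residue differ by exactly the per-residue twist. For a
#' flexible linker the orientation is decoupled from the host protein and no
#' rotation angle is defined: `NA` is returned and downstream predictions
#' are length-independent (isotropic wobble).
#'
#' @param spec A [linker_spec()].
#' @return Rotation in degrees (mod 360) for rigid linkers; `NA_real_` for
#'   flexible linkers.
#' @export
#' @examples
#' dipole_rotation_deg(linker_spec("rigid", 1))  # 103
#' dipole_rotation_deg(linker_spec("flexible", 1))  # NA
dipole_rotation_deg <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  if (spec$kind == "flexible") return(NA_real_)
  (spec$length_residues * spec$rotation_per_residue_deg) %% 360
}

#' Is the dipole orientation decoupled from the host protein?
#'
#' @param spec A [linker_spec()].
#' @return `TRUE` for flexible linkers.
#' @export
is_isotropic <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  spec$kind == "flexible"
}

#' Dipole ensemble implied by a linker and its attachment geometry
#'
#' For a rigid linker the mean dipole direction is obtained by placing a
#' vector at angle `beta` from the helix axis and rotating it by
#' `phi = phase_deg + dipole_rotation_deg(spec)` about the helix axis (which
#' itself sits at `alpha` from z). The spherical law of cosines gives the
#' dipole polar angle:
#' `cos(theta_d) = cos(alpha) cos(beta) - sin(alpha) sin(beta) cos(phi)`,
#' with `phi` measured right-handed about the helix axis from the reference
#' direction in the helix-z plane. A small residual wobble (default 15
#' degrees half-angle) models the imperfect rigidity of real fusions and
#' keeps the s-projection finite. For a flexible linker the ensemble wobbles
#' isotropically (90-degree cone) and the mean angle is irrelevant.
#'
#' @param geometry An [attachment_geometry()].
#' @param spec A [linker_spec()].
#' @param brightness Expected peak photon count per summed image at unit
#'   excitation.
#' @param rigid_wobble_deg Residual wobble half-angle for rigid linkers.
#' @return A [dipole_ensemble()].
#' @export
dipole_ensemble_for <- function(geometry, spec, brightness = 1,
                                rigid_wobble_deg = 15) {
  stopifnot(inherits(geometry, "attachment_geometry"),
            inherits(spec, "linker_spec"))
  if (is_isotropic(spec)) {
    # magic-angle placeholder; predictions do not depend on it at 90 wobble
    return(dipole_ensemble(polar_angle_deg = 54.7356,
                           wobble_half_angle_deg = 90,
                           brightness = brightness))
  }
  a <- deg2rad(geometry$helix_axis_polar_deg)
  b <- deg2rad(geometry$dipole_tilt_deg)
  phi <- deg2rad(geometry$phase_deg + dipole_rotation_deg(spec))
  cos_td <- cos(a) * cos(b) - sin(a) * sin(b) * cos(phi)
  cos_td <- min(1, max(-1, cos_td))
  dipole_ensemble(polar_angle_deg = rad2deg(acos(cos_td)),
                  wobble_half_angle_deg = rigid_wobble_deg,
                  brightness = brightness)
}
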