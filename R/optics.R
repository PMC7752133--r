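# Physical forward model: evanescent-field polarization components under
# azimuthal beam scanning, the cos^2 dipole excitation law, and closed-form
# p:s ratio prediction for oriented, wobbling dipole ensembles.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Optical configuration for through-the-objective TIR excitation
#'
#' Bundles the parameters of the total-internal-reflection excitation path:
#' objective numerical aperture, refractive indices on the glass and sample
#' sides, the beam incidence angle, the excitation wavelength, and the number
#' of discrete azimuth directions used to average the azimuthally scanned
#' beam. The incidence angle must exceed the critical angle
#' `asin(n_sample / n_incident)` so that an evanescent field exists.
#'
#' Defaults describe a 1.49 NA oil objective (glass/immersion index 1.52)
#' imaging a cell (index 1.38) with 488 nm excitation at a representative
#' supercritical incidence angle of 72 degrees.
#'
#' @param numerical_aperture Objective NA (dimensionless, must not exceed
#'   `n_incident`).
#' @param n_incident Refractive index on the incident (glass) side.
#' @param n_sample Refractive index on the sample (cell) side.
#' @param incidence_angle_deg Beam angle from the optical axis, degrees;
#'   must be supercritical.
#' @param wavelength_nm Excitation wavelength in nm.
#' @param azimuth_steps Number of equally spaced beam azimuths used for the
#'   discrete azimuth average (>= 4).
#' @return An object of class `optical_config`.
#' @export
#' @examples
#' cfg <- optical_config()
#' evanescent_field(cfg, "p")
optical_config <- function(numerical_aperture = 1.49, n_incident = 1.52,
                           n_sample = 1.38, incidence_angle_deg = 72,
                           wavelength_nm = 488, azimuth_steps = 36) {
  stopifnot(numerical_aperture > 0, n_incident > 0, n_sample > 0,
            wavelength_nm > 0)
  if (numerical_aperture > n_incident) {
    stop("numerical_aperture must not exceed n_incident", call. = FALSE)
  }
  if (azimuth_steps < 4) {
    stop("azimuth_steps must be at least 4", call. = FALSE)
  }
  critical_deg <- rad2deg(asin(n_sample / n_incident))
  if (incidence_angle_deg <= critical_deg) {
    stop(sprintf(
      "not total internal reflection: incidence angle %.2f deg is not above the critical angle %.2f deg",
      incidence_angle_deg, critical_deg), call. = FALSE)
  }
  structure(
    list(numerical_aperture = numerical_aperture,
         n_incident = n_incident,
         n_sample = n_sample,
         incidence_angle_deg = incidence_angle_deg,
         wavelength_nm = wavelength_nm,
         azimuth_steps = as.integer(azimuth_steps)),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> NA %.2f, n %.2f/%.2f, incidence %.1f deg, %d nm, %d azimuths\n",
    x$numerical_aperture, x$n_incident, x$n_sample, x$incidence_angle_deg,
    x$wavelength_nm, x$azimuth_steps))
  invisible(x)
}

#' Azimuth-averaged evanescent excitation field for one polarization
#'
#' Computes the relative excitation intensity components of the evanescent
#' field along the lab axes (z = optical axis = nucleocytoplasmic axis of a
#' basal-surface NPC) for p- or s-polarized TIR excitation, averaged over
#' `azimuth_steps` equally spaced azimuths of the scanned beam. Intensities
#' follow the standard Fresnel evanescent-wave expressions; the in-plane and
#' axial parts of the p field are 90 degrees out of phase and therefore add
#' incoherently, as do contributions from distinct beam azimuths (the scan
#' period is much shorter than the exposure).
#'
#' After azimuth averaging the in-plane components are equal (`ix == iy`);
#' the s field has no axial component. The 1/e intensity penetration depth is
#' `wavelength / (4 * pi * sqrt(n_incident^2 * sin^2(theta) - n_sample^2))`.
#'
#' @param config An [optical_config()].
#' @param pol `"p"` or `"s"`.
#' @return An object of class `evanescent_field`: a list with `pol_label`,
#'   `ix`, `iy`, `iz` (relative intensities) and `penetration_depth_nm`.
#' @export
evanescent_field <- function(config, pol = c("p", "s")) {
  stopifnot(inherits(config, "optical_config"))
  pol <- match.arg(pol)
  th <- deg2rad(config$incidence_angle_deg)
  n <- config$n_sample / config$n_incident
  s2 <- sin(th)^2
  c2 <- cos(th)^2
  # Per-azimuth evanescent intensities (unit incident intensity), with the
  # beam propagating along +x in its own frame.
  i_s <- 4 * c2 / (1 - n^2)                      # field along y
  denom <- n^4 * c2 + s2 - n^2
  i_px <- 4 * c2 * (s2 - n^2) / denom            # in-plane, along propagation
  i_pz <- 4 * c2 * s2 / denom                    # axial
  k <- config$azimuth_steps
  phi <- 2 * pi * (seq_len(k) - 1) / k
  if (pol == "s") {
    # s field direction is in-plane, perpendicular to the beam azimuth
    ix <- mean(i_s * sin(phi)^2)
    iy <- mean(i_s * cos(phi)^2)
    iz <- 0
  } else {
    ix <- mean(i_px * cos(phi)^2)
    iy <- mean(i_px * sin(phi)^2)
    iz <- i_pz
  }
  depth <- config$wavelength_nm /
    (4 * pi * sqrt(config$n_incident^2 * s2 - config$n_sample^2))
  structure(
    list(pol_label = pol, ix = ix, iy = iy, iz = iz,
         penetration_depth_nm = depth),
    class = "evanescent_field")
}

#' @export
print.evanescent_field <- function(x, ...) {
  cat(sprintf(
    "<evanescent_field> %s: ix %.4f, iy %.4f, iz %.4f, depth %.0f nm\n",
    x$pol_label, x$ix, x$iy, x$iz, x$penetration_depth_nm))
  invisible(x)
}

#' Unit vector in the lab frame
#'
#' @param x,y,z Components; the vector must have unit norm to within 1e-9.
#' @return A named numeric vector of class `unit_vector3`.
#' @export
unit_vector <- function(x, y, z) {
  v <- c(x = x, y = y, z = z)
  if (abs(sqrt(sum(v^2)) - 1) > 1e-9) {
    stop("vector is not unit norm (tolerance 1e-9)", call. = FALSE)
  }
  structure(v, class = "unit_vector3")
}

#' Excitation rate of a dipole in a linearly polarized field
#'
#' The absorption probability of a fluorophore is proportional to
#' cos^2(Theta), where Theta is the angle between the excitation field
#' direction and the excitation transition dipole.
#'
#' @param field_dir Unit vector of the field direction ([unit_vector()]).
#' @param field_intensity Non-negative relative field intensity.
#' @param dipole_dir Unit vector of the dipole axis.
#' @return `field_intensity * cos^2(Theta)`; symmetric under dipole sign flip.
#' @export
#' @examples
#' excitation_rate(unit_vector(0, 0, 1), 1, unit_vector(0, 0, 1))  # 1
#' excitation_rate(unit_vector(0, 0, 1), 1, unit_vector(1, 0, 0))  # 0
excitation_rate <- function(field_dir, field_intensity, dipole_dir) {
  for (v in list(field_dir, dipole_dir)) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-9) {
      stop("field_dir and dipole_dir must be unit vectors", call. = FALSE)
    }
  }
  stopifnot(field_intensity >= 0)
  field_intensity * sum(field_dir * dipole_dir)^2
}

#' Oriented, wobbling dipole ensemble of one NPC sensor
#'
#' Describes the mEGFP excitation dipoles of one nuclear pore complex: a mean
#' dipole polar angle from the z (nucleocytoplasmic) axis, an azimuthal
#' offset, `n_fold` rotationally symmetric copies (eight for the NPC), fast
#' wobble within a uniform solid-angle cone, and a brightness giving the
#' expected peak photon count per summed image at unit excitation.
#'
#' @param polar_angle_deg Mean dipole angle from z, in `[0, 180]` degrees.
#' @param azimuth_offset_deg Mean azimuth of the first copy (degrees). With
#'   azimuth-averaged excitation fields this does not affect predictions.
#' @param n_fold Number of rotationally symmetric copies (>= 1, default 8).
#' @param wobble_half_angle_deg Half-angle of the wobble cone, `[0, 90]`.
#' @param brightness Expected peak photon count per summed image at unit
#'   excitation (>= 0).
#' @return An object of class `dipole_ensemble`.
#' @export
dipole_ensemble <- function(polar_angle_deg, azimuth_offset_deg = 0,
                            n_fold = 8, wobble_half_angle_deg = 0,
                            brightness = 1) {
  stopifnot(polar_angle_deg >= 0, polar_angle_deg <= 180,
            wobble_half_angle_deg >= 0, wobble_half_angle_deg <= 90,
            n_fold >= 1, brightness >= 0)
  structure(
    list(polar_angle_deg = polar_angle_deg,
         azimuth_offset_deg = azimuth_offset_deg,
         n_fold = as.integer(n_fold),
         wobble_half_angle_deg = wobble_half_angle_deg,
         brightness = brightness),
    class = "dipole_ensemble")
}

# Orientational order parameter <P2(cos gamma)> of a uniform solid-angle
# wobble cone of half-angle w: S = cos(w) (1 + cos(w)) / 2.
wobble_order_parameter <- function(wobble_half_angle_deg) {
  cw <- cos(deg2rad(wobble_half_angle_deg))
  cw * (1 + cw) / 2
}

# <cos^2 theta_lab> of the dipole axis for a mean polar angle theta_d and a
# uniform wobble cone, via the addition theorem for second moments:
# <P2(cos theta_lab)> = P2(cos theta_d) * S(w).
mean_cos2_z <- function(polar_angle_deg, wobble_half_angle_deg) {
  p2 <- (3 * cos(deg2rad(polar_angle_deg))^2 - 1) / 2
  s <- wobble_order_parameter(wobble_half_angle_deg)
  1 / 3 + (2 / 3) * p2 * s
}

#' Expected excitation signal of an ensemble in one field
#'
#' The per-polarization signal is `ix * <sin^2 theta> + iz * <cos^2 theta>`,
#' with the angular brackets averaging over the wobble cone and the n-fold
#' symmetric copies. Requires an azimuth-averaged field (`ix == iy`), under
#' which the in-plane second moments collapse and the azimuth offset and
#' copy number drop out.
#'
#' @param ensemble A [dipole_ensemble()].
#' @param field An [evanescent_field()].
#' @return Non-negative relative signal (per copy; copy number rescales both
#'   polarizations identically and is left out).
#' @export
ensemble_signal <- function(ensemble, field) {
  stopifnot(inherits(ensemble, "dipole_ensemble"),
            inherits(field, "evanescent_field"))
  if (abs(field$ix - field$iy) > 1e-9 * max(field$ix, field$iy, 1e-12)) {
    stop("field must be azimuth-averaged (ix == iy)", call. = FALSE)
  }
  c2 <- mean_cos2_z(ensemble$polar_angle_deg, ensemble$wobble_half_angle_deg)
  field$ix * (1 - c2) + field$iz * c2
}

#' Predicted p:s excitation ratio for a dipole ensemble
#'
#' Closed-form forward prediction of the per-punctum p:s ratio: the ratio of
#' expected excitation signals under the azimuth-averaged p and s evanescent
#' fields. Because the fields are azimuth-averaged the result is independent
#' of the ensemble's azimuth offset and of the copy number.
#'
#' A dipole exactly along the optical axis with zero wobble has no projection
#' on the s field; the ratio is then undefined and an error is raised rather
#' than returning infinity.
#'
#' @param ensemble A [dipole_ensemble()].
#' @param field_p,field_s Azimuth-averaged p and s [evanescent_field()]s.
#' @return Dimensionless p:s ratio.
#' @export
#' @examples
#' cfg <- optical_config()
#' fp <- evanescent_field(cfg, "p")
#' fs <- evanescent_field(cfg, "s")
#' predict_ps_ratio(dipole_ensemble(90), fp, fs)
predict_ps_ratio <- function(ensemble, field_p, field_s) {
  signal_p <- ensemble_signal(ensemble, field_p)
  signal_s <- ensemble_signal(ensemble, field_s)
  if (signal_s <= 1e-12 * max(signal_p, 1)) {
    stop("undefined ratio: ensemble has no projection on the s field",
         call. = FALSE)
  }
  signal_p / signal_s
}
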