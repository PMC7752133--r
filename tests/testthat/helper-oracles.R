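# Shared fixtures and independent oracles.

# internal helpers exercised directly in tests
add_gaussian_spot <- poltirf:::add_gaussian_spot
mean_cos2_z <- poltirf:::mean_cos2_z

default_fields <- function(optics = optical_config()) {
  list(p = evanescent_field(optics, "p"), s = evanescent_field(optics, "s"))
}

# Monte-Carlo oracle for the p:s ratio: sample dipole directions uniformly
# in the wobble cone about a mean axis at the given polar angle, average
# cos^2 excitation rates component-wise against the azimuth-averaged fields.
mc_ps_ratio <- function(theta_deg, wobble_deg, fields, n = 2e5) {
  a <- theta_deg * pi / 180
  cw <- cos(wobble_deg * pi / 180)
  cg <- stats::runif(n, cw, 1)            # uniform in solid angle
  sg <- sqrt(1 - cg^2)
  ph <- stats::runif(n, 0, 2 * pi)
  # mean axis (sin a, 0, cos a); cone frame e1 = (cos a, 0, -sin a),
  # e2 = (0, 1, 0)
  dx <- cg * sin(a) + sg * cos(ph) * cos(a)
  dy <- sg * sin(ph)
  dz <- cg * cos(a) - sg * cos(ph) * sin(a)
  rp <- mean(fields$p$ix * dx^2 + fields$p$iy * dy^2 + fields$p$iz * dz^2)
  rs <- mean(fields$s$ix * dx^2 + fields$s$iy * dy^2 + fields$s$iz * dz^2)
  rp / rs
}

# Rotation-matrix oracle for the linker dipole polar angle: build the dipole
# direction by explicit 3x3 rotations (Rodrigues about the helix axis) and
# return its polar angle in degrees.
rotation_matrix_theta_d <- function(alpha_deg, beta_deg, phi_deg) {
  d2r <- pi / 180
  a <- alpha_deg * d2r; b <- beta_deg * d2r; phi <- phi_deg * d2r
  u <- c(sin(a), 0, cos(a))                     # helix axis
  e1 <- c(cos(a), 0, -sin(a))                   # reference perpendicular
  d0 <- cos(b) * u + sin(b) * e1                # dipole at phi = 0
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  rot <- diag(3) * cos(phi) + sin(phi) * ux + (1 - cos(phi)) * (u %o% u)
  d <- rot %*% d0
  acos(max(-1, min(1, d[3]))) / d2r
}

# Direct-sum correlation with replicate padding: the brute-force oracle for
# the FFT-based LoG response.
direct_correlate <- function(img, kernel) {
  kh <- (nrow(kernel) - 1) / 2
  kw <- (ncol(kernel) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2 * kh, w + 2 * kw)
  pad[(kh + 1):(kh + h), (kw + 1):(kw + w)] <- img
  pad[1:kh, ] <- pad[rep(kh + 1, kh), ]
  pad[(kh + h + 1):(kh + h + kh), ] <- pad[rep(kh + h, kh), ]
  pad[, 1:kw] <- pad[, rep(kw + 1, kw)]
  pad[, (kw + w + 1):(kw + w + kw)] <- pad[, rep(kw + w, kw)]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- sum(pad[i:(i + 2 * kh), j:(j + 2 * kw)] * kernel)
  }
  out
}

# Compact scene used widely in tests: fewer NPCs on a smaller field.
small_scene <- function(seed = 1, n_npcs = 12, ...) {
  scene_spec(image_shape_px = c(96, 96), n_npcs = n_npcs, seed = seed, ...)
}

default_config_for <- function(scene, ...) {
  analysis_config(roi = scene$nuclear_roi, ...)
}
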