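# Shared oracles and fixture builders. Oracles are written independently of
# the implementation paths they check.

# Step-by-step CIE L* for a grey sRGB level g in [0,1]: decompand, take Y,
# apply the L* formula. Independent of srgb_to_lab's vectorised path.
oracle_grey_L <- function(g) {
  y <- if (g <= 0.04045) g / 12.92 else ((g + 0.055) / 1.055)^2.4
  if (y > (6 / 29)^3) 116 * y^(1 / 3) - 16 else (29 / 3)^3 * y / 100 * 100
}

# Brute-force enumeration of the seven decision regions as independent
# predicates (the printed rules with the documented tie/overlap resolutions).
# Returns an n x 7 logical matrix: point i satisfies rule j.
oracle_rule_matrix <- function(L, B) {
  cbind(
    B > 11 & L >= 40,                              # 1
    B > 11 & L < 40,                               # 2
    B <= 11 & L < 32.5,                            # 3
    B <= 11 & L >= 32.5 & L < 75 & B >= 6.5,       # 4
    B <= 11 & L >= 32.5 & L < 75 & B < 6.5,        # 5
    B <= 11 & L >= 75 & L <= -25 * B + 200,        # 6
    B <= 11 & L >= 75 & L > -25 * B + 200          # 7
  )
}

# Random well-conditioned 3x3 channel-mixing distortion with rows summing to
# one (keeps linear-RGB values in [0,1]).
random_distortion <- function(strength = 0.2) {
  R <- matrix(stats::runif(9), 3, 3)
  R <- R / rowSums(R)
  (1 - strength) * diag(3) + strength * R
}

# Distort reference chart colours in linear RGB and recompand.
distort_colours <- function(ref_unit, D) {
  lin <- bonetemp:::.srgb_decompand(ref_unit)
  mixed <- lin %*% t(D)
  bonetemp:::.srgb_compand(pmin(pmax(mixed, 0), 1))
}

# Disk image of the given interior Lab colour (radius in px at 300 dpi).
disk_image <- function(lab = c(60, 2, 5), radius_px = 50, dpi = 300, ...) {
  render_sample_image(lab, radius_mm = radius_px * 25.4 / dpi, dpi = dpi, ...)
}
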