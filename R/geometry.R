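#' Fixed-bend scrunching geometry model
#'
#' Idealized straight-arm B-DNA geometry for the dual-labelled promoter
#' template: two arms meet at the bend point with a fixed angle; only the
#' downstream arm shortens as bases are pulled into the complex
#' (scrunched).  This replaces a coordinate-based calculation on a
#' reference crystal structure; the bend angle is meant to be calibrated
#' so the unscrunched (position 0) model distance matches the measured
#' open-state distance.
#'
#' @param rise_per_bp helical rise (nm/bp, default 0.34).
#' @param bend_angle angle between the upstream and downstream arms
#'   (degrees, in (0, 180]).
#' @param upstream_arm_bp,downstream_arm_bp base pairs from the bend point
#'   to each label.
#' @param forster_radius Forster radius R0 (nm); the default 6.0 nm is a
#'   typical value for a Cy3/Cy5-like pair, not a measured one.
#' @return An object of class `geometry_model`.
#' @export
geometry_model <- function(rise_per_bp = 0.34, bend_angle = 90,
                           upstream_arm_bp = 16, downstream_arm_bp = 16,
                           forster_radius = 6.0) {
  stop_if_not(upstream_arm_bp > 0 && downstream_arm_bp > 0, "arms must be > 0")
  stop_if_not(bend_angle > 0 && bend_angle <= 180,
              "bend_angle must lie in (0, 180] degrees")
  stop_if_not(forster_radius > 0, "forster_radius must be > 0")
  structure(list(rise_per_bp = rise_per_bp, bend_angle = bend_angle,
                 upstream_arm_bp = upstream_arm_bp,
                 downstream_arm_bp = downstream_arm_bp,
                 forster_radius = forster_radius),
            class = "geometry_model")
}

#' Convert FRET efficiency to an apparent donor-acceptor distance
#'
#' `R = R0 (1/E - 1)^(1/6)`, strictly decreasing in E.
#'
#' @param e gamma-corrected FRET efficiency, strictly inside (0, 1).
#' @param r0 Forster radius (nm).
#' @return Distance in nm.
#' @export
fret_to_distance <- function(e, r0) {
  stop_if_not(all(e > 0 & e < 1),
              "E must lie strictly inside (0, 1); boundary efficiencies carry no distance information")
  r0 * (1 / e - 1)^(1 / 6)
}

#' Inverse of [fret_to_distance()]
#' @param r distance (nm), > 0.
#' @param r0 Forster radius (nm).
#' @return FRET efficiency in (0, 1).
#' @export
distance_to_fret <- function(r, r0) {
  stop_if_not(all(r > 0), "distance must be > 0")
  1 / (1 + (r / r0)^6)
}

#' Average distances from the two template labelling sets
#'
#' The two template families place the downstream label on opposite
#' strands; averaging their donor-acceptor distances mitigates the DNA
#' twist contribution.  The error combines half the difference between
#' the two estimates with the propagated input errors in quadrature.
#'
#' @param d_templateI_II,d_NT distances (nm) from the two template sets.
#' @param se_1,se_2 their standard errors (optional).
#' @return List with `distance` and `se`.
#' @export
average_template_distances <- function(d_templateI_II, d_NT,
                                       se_1 = 0, se_2 = 0) {
  stop_if_not(is.finite(d_templateI_II) && is.finite(d_NT),
              "distances must be finite")
  halfdiff <- abs(d_templateI_II - d_NT) / 2
  list(distance = (d_templateI_II + d_NT) / 2,
       se = sqrt(halfdiff^2 + (se_1^2 + se_2^2) / 4))
}

#' Model donor-acceptor distance at a stalling position
#'
#' Straight arms of B-DNA meet at the bend with angle theta; scrunching
#' pulls `scrunched_bases(n)` bases into the complex, shortening only the
#' downstream arm.  The label distance follows the law of cosines,
#' `d = sqrt(a^2 + b^2 - 2 a b cos(theta))`.
#'
#' @param n stalling position (RNA length).
#' @param g a [geometry_model()].
#' @param scrunched_bases function mapping position to bases pulled in;
#'   default `n - 1` (the first nucleotide does not scrunch), with 0 at
#'   n = 0.
#' @return Distance in nm.  Over-scrunching (downstream arm used up) is
#'   rejected.
#' @export
scrunch_model_distance <- function(n, g, scrunched_bases = NULL) {
  stop_if_not(inherits(g, "geometry_model"), "g must be a geometry_model")
  sb <- scrunched_bases %||% function(n) max(n - 1, 0)
  nb <- sb(n)
  stop_if_not(nb < g$downstream_arm_bp,
              "over-scrunching: downstream arm would vanish")
  a <- g$upstream_arm_bp * g$rise_per_bp
  b <- (g$downstream_arm_bp - nb) * g$rise_per_bp
  th <- g$bend_angle * pi / 180
  sqrt(a^2 + b^2 - 2 * a * b * cos(th))
}

#' Calibrate the bend angle so the unscrunched model matches a distance
#'
#' Solves for the arm angle at which [scrunch_model_distance()] at
#' position 0 equals the measured open-state distance.
#'
#' @param d0 measured distance at position 0 (nm).
#' @param g a [geometry_model()] (its `bend_angle` is ignored).
#' @return A new `geometry_model` with the calibrated angle.
#' @export
calibrate_bend_angle <- function(d0, g) {
  a <- g$upstream_arm_bp * g$rise_per_bp
  b <- g$downstream_arm_bp * g$rise_per_bp
  cth <- (a^2 + b^2 - d0^2) / (2 * a * b)
  stop_if_not(cth >= -1 && cth < 1,
              "target distance unreachable with these arm lengths")
  g$bend_angle <- acos(cth) * 180 / pi
  g
}
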