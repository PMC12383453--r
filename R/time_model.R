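#' Reconstruct per-segment delivery dynamics of an arc
#'
#' RTPLAN files store geometry and cumulative meterset, not time. Delivery
#' time is reconstructed per segment (between adjacent control points) as the
#' slowest of the three axis constraints, assuming each axis runs at its
#' limit when it is the bottleneck:
#' \deqn{t_k = \max\left(\frac{\Delta MU_k}{DR_{max}} 60,\;
#'   \frac{|\Delta\theta_k|}{GS_{max}},\;
#'   \frac{\max_i |\Delta x_{ik}|}{10\, v_{max}}\right)}
#' with \eqn{\Delta MU} in MU, \eqn{DR_{max}} in MU/min, gantry in deg,
#' leaf travel in mm and \eqn{v_{max}} in cm/s. Dose rate, gantry speed and
#' leaf speeds then follow by division.
#'
#' @param arc an [arc_beam()].
#' @param machine a [machine_spec()].
#' @return an object of class `segment_dynamics`: a list with per-segment
#'   vectors `delta_mu` (MU), `delta_gantry` (deg, signed), `duration` (s),
#'   `dose_rate` (MU/min), `gantry_speed` (deg/s), and matrix `leaf_speed`
#'   (`n_seg x 2*n_pairs`, cm/s, bank A columns then bank B), plus
#'   `leaf_travel` (same shape, mm) and `open_pair` (`n_seg x n_pairs`
#'   logical: pair open in at least one bounding control point).
#' @export
segment_time_model <- function(arc, machine = arc$machine) {
  n_cp <- n_control_points(arc)
  dmu <- diff(arc$cum_weight) * arc$total_mu
  dg <- gantry_increments(arc$gantry_angle)
  travel <- cbind(abs(diff(arc$bankA)), abs(diff(arc$bankB)))  # mm
  max_travel <- row_max(travel)
  t_mu <- dmu / machine$max_dose_rate * 60
  t_g <- abs(dg) / machine$max_gantry_speed
  t_leaf <- max_travel / (10 * machine$max_leaf_speed)
  duration <- pmax(t_mu, t_g, t_leaf)
  if (any(duration <= 0))
    stop("zero-duration segment: no MU, gantry motion, or leaf motion at ",
         "segment ", which(duration <= 0)[1])
  open_cp <- open_pairs(arc, machine)        # n_cp x n_pairs
  out <- list(
    delta_mu = dmu,
    delta_gantry = dg,
    duration = duration,
    dose_rate = dmu / duration * 60,
    gantry_speed = abs(dg) / duration,
    leaf_speed = travel / duration / 10,
    leaf_travel = travel,
    open_pair = open_cp[-n_cp, , drop = FALSE] |
                open_cp[-1, , drop = FALSE],
    arc_length = arc_length_deg(arc$gantry_angle),
    total_mu = arc$total_mu)
  class(out) <- "segment_dynamics"
  out
}

# logical n_cp x n_pairs: pair is open (contributes to the aperture) at a CP.
# A pair is closed when its gap <= min_gap or it lies fully outside the
# Y-jaw aperture.
open_pairs <- function(arc, machine = arc$machine) {
  gap <- arc$bankB - arc$bankA
  b <- machine$boundaries
  lo <- matrix(b[-length(b)], nrow(gap), machine$n_pairs, byrow = TRUE)
  hi <- matrix(b[-1],         nrow(gap), machine$n_pairs, byrow = TRUE)
  in_y <- (hi > arc$jaws[, "y1"]) & (lo < arc$jaws[, "y2"])
  gap > machine$min_gap & in_y
}
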