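#' Construct a dynamic arc beam
#'
#' An `arc_beam` is the unit of prediction: an ordered sequence of MLC control
#' points delivered while the gantry rotates, with its monitor units and
#' prescription context. Leaf positions follow the RTPLAN convention: bank A
#' is the left bank (more negative X), bank B the right bank, so the leaf gap
#' of pair *i* is `bankB[i] - bankA[i] >= 0`. Positions are in mm at the
#' isocenter plane.
#'
#' @param arc_id character arc identifier, unique within a cohort.
#' @param patient_id character patient identifier.
#' @param treatment_date a `Date`.
#' @param cum_weight numeric vector of cumulative meterset weights, one per
#'   control point, non-decreasing, first 0 and last 1.
#' @param gantry_angle numeric vector of gantry angles, deg (IEC, stored as
#'   given; arc length is computed on the unwrapped trajectory).
#' @param bankA,bankB numeric matrices `n_cp x n_pairs` of leaf positions, mm.
#' @param jaws numeric matrix `n_cp x 4` (columns x1, x2, y1, y2, mm) or a
#'   length-4 vector recycled to all control points.
#' @param total_mu total beam monitor units.
#' @param dose_per_fraction prescribed dose per fraction, Gy.
#' @param machine a [machine_spec()].
#' @return an object of class `arc_beam`.
#' @export
arc_beam <- function(arc_id, patient_id, treatment_date,
                     cum_weight, gantry_angle, bankA, bankB, jaws,
                     total_mu, dose_per_fraction,
                     machine = machine_spec()) {
  stopifnot(inherits(machine, "machine_spec"))
  bankA <- as.matrix(bankA); bankB <- as.matrix(bankB)
  n_cp <- length(cum_weight)
  if (n_cp < 2) stop("an arc needs at least 2 control points")
  if (length(gantry_angle) != n_cp ||
      nrow(bankA) != n_cp || nrow(bankB) != n_cp)
    stop("control-point fields have inconsistent lengths")
  if (ncol(bankA) != machine$n_pairs || ncol(bankB) != machine$n_pairs)
    stop("leaf banks must have one column per machine leaf pair")
  if (is.null(dim(jaws))) jaws <- matrix(jaws, n_cp, 4, byrow = TRUE)
  jaws <- as.matrix(jaws)
  if (nrow(jaws) != n_cp || ncol(jaws) != 4)
    stop("jaws must be n_cp x 4 (x1, x2, y1, y2)")
  colnames(jaws) <- c("x1", "x2", "y1", "y2")
  if (any(diff(cum_weight) < -1e-9))
    stop("cumulative meterset weight must be non-decreasing")
  if (abs(cum_weight[1]) > 1e-6 || abs(cum_weight[n_cp] - 1) > 1e-6)
    stop("cumulative meterset weight must start at 0 and end at 1")
  if (!is.finite(total_mu) || total_mu <= 0) stop("total_mu must be > 0")
  if (!is.finite(dose_per_fraction) || dose_per_fraction <= 0)
    stop("dose_per_fraction must be > 0")
  if (arc_length_deg(gantry_angle) <= 0)
    stop("arc length must be > 0 (static beams are not arcs)")
  x <- list(arc_id = as.character(arc_id),
            patient_id = as.character(patient_id),
            treatment_date = as.Date(treatment_date),
            cum_weight = as.numeric(cum_weight),
            gantry_angle = as.numeric(gantry_angle),
            bankA = bankA, bankB = bankB, jaws = jaws,
            total_mu = as.numeric(total_mu),
            dose_per_fraction = as.numeric(dose_per_fraction),
            machine = machine)
  class(x) <- "arc_beam"
  x
}

#' @export
print.arc_beam <- function(x, ...) {
  cat("<arc_beam> ", x$arc_id, " (patient ", x$patient_id, ", ",
      format(x$treatment_date), ")\n", sep = "")
  cat("  ", n_control_points(x), " control points, ",
      round(arc_length_deg(x$gantry_angle), 1), " deg arc, ",
      round(x$total_mu, 1), " MU, ", x$dose_per_fraction, " Gy/fx\n",
      sep = "")
  invisible(x)
}

#' @rdname arc_beam
#' @param arc an `arc_beam`.
#' @export
n_control_points <- function(arc) length(arc$cum_weight)

#' Total gantry travel of an angle sequence, deg
#'
#' Sum of absolute gantry increments, unwrapping across the 0/360 seam (an
#' increment is never taken longer than the short way around).
#'
#' @param gantry_angle numeric vector of gantry angles, deg.
#' @return arc length in degrees.
#' @export
arc_length_deg <- function(gantry_angle) {
  d <- diff(gantry_angle) %% 360
  d <- pmin(d, 360 - d)
  sum(abs(d))
}

# signed, unwrapped gantry increments (shortest way), deg
gantry_increments <- function(gantry_angle) {
  d <- diff(gantry_angle) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Construct a QA record for an arc
#'
#' @param arc_id character arc identifier.
#' @param measured_gpr measured gamma passing rate, percent in \[0, 100\].
#' @param criteria a [gamma_criteria()] describing how the GPR was computed.
#' @param action_limit GPR action limit, percent; an arc fails QA when
#'   `measured_gpr < action_limit`.
#' @return a one-row data.frame with columns `arc_id`, `measured_gpr`,
#'   `pass_label` (TRUE = pass) and attribute `criteria`.
#' @export
qa_record <- function(arc_id, measured_gpr, criteria = gamma_criteria(),
                      action_limit = 95) {
  if (any(measured_gpr < 0 | measured_gpr > 100))
    stop("measured_gpr must be in [0, 100]")
  out <- data.frame(arc_id = as.character(arc_id),
                    measured_gpr = as.numeric(measured_gpr),
                    pass_label = measured_gpr >= action_limit,
                    stringsAsFactors = FALSE)
  attr(out, "criteria") <- criteria
  attr(out, "action_limit") <- action_limit
  out
}

#' Validate an arc against machine constraints
#'
#' Checks, per control point and segment: leaf pairs not crossed
#' (`bankB >= bankA`), open gaps at least `min_gap`, leaf tips within the
#' machine field extent, cumulative meterset weight monotone, and implied
#' per-segment leaf speeds within `max_leaf_speed` under the delivery-time
#' model of [segment_time_model()]. Violations are returned as data, not
#' raised as errors.
#'
#' @param arc an [arc_beam()].
#' @param machine a [machine_spec()]; defaults to the arc's own machine.
#' @param tol numerical tolerance, mm (positions) / relative (speeds).
#' @return a data.frame of violations with columns `type`, `control_point`,
#'   `pair`, `detail`; zero rows when the arc is valid.
#' @export
validate_arc <- function(arc, machine = arc$machine, tol = 1e-6) {
  gap <- arc$bankB - arc$bankA
  v <- list()
  add <- function(type, cp, pair, detail) {
    v[[length(v) + 1L]] <<- data.frame(type = type, control_point = cp,
                                       pair = pair, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  crossed <- which(gap < -tol, arr.ind = TRUE)
  if (nrow(crossed))
    add("crossed_pair", crossed[, 1], crossed[, 2],
        sprintf("gap %.3f mm < 0", gap[crossed]))
  # a pair must either be closed (gap ~ 0) or hold at least min_gap
  partial <- which(gap > tol & gap < machine$min_gap - tol, arr.ind = TRUE)
  if (nrow(partial))
    add("sub_min_gap", partial[, 1], partial[, 2],
        sprintf("open gap %.3f mm < min_gap %.3f mm",
                gap[partial], machine$min_gap))
  out_of_field <- which(abs(arc$bankA) > machine$field_extent + tol |
                        abs(arc$bankB) > machine$field_extent + tol,
                        arr.ind = TRUE)
  if (nrow(out_of_field))
    add("out_of_field", out_of_field[, 1], out_of_field[, 2],
        "leaf position beyond field extent")
  if (any(diff(arc$cum_weight) < -tol))
    add("non_monotone_weight", which(diff(arc$cum_weight) < -tol)[1] + 1L,
        NA_integer_, "cumulative meterset weight decreases")
  dyn <- try(segment_time_model(arc, machine), silent = TRUE)
  if (!inherits(dyn, "try-error")) {
    vmax <- machine$max_leaf_speed * (1 + 1e-6)
    fast <- which(dyn$leaf_speed > vmax, arr.ind = TRUE)
    if (nrow(fast))
      add("leaf_speed", fast[, 1], ((fast[, 2] - 1L) %% machine$n_pairs) + 1L,
          sprintf("implied speed %.3f cm/s > %.3f cm/s",
                  dyn$leaf_speed[fast], machine$max_leaf_speed))
  }
  if (!length(v))
    return(data.frame(type = character(), control_point = integer(),
                      pair = integer(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}
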