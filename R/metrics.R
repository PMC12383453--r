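#' @name complexity_metrics
#' @title Plan-complexity metrics for dynamic arcs
#'
#' @description
#' Eighteen per-arc features computed from control-point geometry and the
#' delivery-time model: two static parameters (aperture area, MU per Gy),
#' six dynamic parameters (means and modulations of MLC speed, dose rate,
#' gantry speed), and ten aperture-complexity metrics (gap quantiles, small
#' aperture score, tongue-and-groove index, modulation complexity score,
#' total modulation index, beam irregularity, beam modulation, edge metric,
#' leaf travel per arc length).
#'
#' Per-control-point quantities are combined into per-segment values by
#' averaging the two bounding control points and weighting by the segment's
#' meterset increment (dose is delivered *between* control points).
NULL

# dMU-weighted mean of a per-CP quantity under segment attribution.
# keep: logical per CP, CPs to include (undefined CPs are dropped; a segment
# uses the mean of its defined endpoints, or is dropped if both undefined).
mu_weighted_cp_mean <- function(percp, dmu, keep = rep(TRUE, length(percp))) {
  n <- length(percp)
  a <- percp[-n]; b <- percp[-1]
  ka <- keep[-n];  kb <- keep[-1]
  seg <- ifelse(ka & kb, (a + b) / 2, ifelse(ka, a, ifelse(kb, b, NA)))
  use <- !is.na(seg) & dmu >= 0
  if (!any(use & dmu > 0)) stop("no weighted segments with defined values")
  sum(dmu[use] * seg[use]) / sum(dmu[use])
}

#' @describeIn complexity_metrics Static parameters: `Area`, the
#'   meterset-weighted mean aperture area (mm^2), and
#'   `MUOverDosePerFraction` (MU/Gy).
#' @param arc an [arc_beam()].
#' @param machine a [machine_spec()].
#' @return `static_metrics`: named numeric of length 2.
#' @export
static_metrics <- function(arc, machine = arc$machine,
                           g = arc_aperture_stats(arc, machine)) {
  if (arc$total_mu <= 0) stop("total MU must be positive")
  dmu <- diff(arc$cum_weight) * arc$total_mu
  c(Area = mu_weighted_cp_mean(g$area, dmu),
    MUOverDosePerFraction = arc$total_mu / arc$dose_per_fraction)
}

#' @describeIn complexity_metrics Dynamic parameters from the segment time
#'   model: `MeanMLCSpeed` (cm/s), `MLCSpeedModulation` (cm/s per mm),
#'   `MeanRR` (MU/min), `RRModulation` (MU/min per deg), `MeanGS` (deg/s),
#'   `GSModulation` (deg/s per deg).
#' @param dyn a `segment_dynamics` from [segment_time_model()].
#' @export
dynamic_metrics <- function(dyn) {
  infield <- cbind(dyn$open_pair, dyn$open_pair)  # bank A cols then bank B
  v <- dyn$leaf_speed
  mean_mlc <- mean(v[infield])
  n_seg <- length(dyn$duration)
  if (n_seg >= 2) {
    both <- infield[-n_seg, , drop = FALSE] & infield[-1, , drop = FALSE]
    dv <- abs(v[-1, , drop = FALSE] - v[-n_seg, , drop = FALSE])
    total_travel <- sum(dyn$leaf_travel[infield])  # mm
    mlc_mod <- if (total_travel > 0) sum(dv[both]) / total_travel else 0
    rr_mod <- sum(abs(diff(dyn$dose_rate))) / dyn$arc_length
    gs_mod <- sum(abs(diff(dyn$gantry_speed))) / dyn$arc_length
  } else {
    mlc_mod <- rr_mod <- gs_mod <- 0
  }
  c(MeanMLCSpeed = mean_mlc,
    MLCSpeedModulation = mlc_mod,
    MeanRR = dyn$total_mu / sum(dyn$duration) * 60,
    RRModulation = rr_mod,
    MeanGS = dyn$arc_length / sum(dyn$duration),
    GSModulation = gs_mod)
}

#' @describeIn complexity_metrics Gap statistics over all open pairs pooled
#'   across control points (unweighted): first quartile and median of the
#'   MLC gap distribution (mm), and `SAS10`, the fraction of gaps strictly
#'   below 10 mm.
#' @param sas_threshold small-aperture threshold, mm.
#' @param mu_weighted pool gaps weighted by control-point meterset share
#'   instead of unweighted (non-default variant).
#' @export
gap_statistics <- function(arc, machine = arc$machine, sas_threshold = 10,
                           mu_weighted = FALSE,
                           g = arc_aperture_stats(arc, machine)) {
  gaps <- g$gap[g$open]
  if (!length(gaps)) stop("arc has no open leaf pairs")
  if (!mu_weighted) {
    q <- stats::quantile(gaps, c(0.25, 0.5), names = FALSE, type = 7)
    sas <- mean(gaps < sas_threshold)
  } else {
    dmu <- diff(arc$cum_weight)
    cpw <- c(dmu / 2, 0) + c(0, dmu / 2)        # trapezoid CP attribution
    wmat <- matrix(cpw, nrow(g$gap), ncol(g$gap))
    w <- wmat[g$open]
    o <- order(gaps); gaps_s <- gaps[o]; w_s <- w[o] / sum(w)
    cw <- cumsum(w_s)
    q <- vapply(c(0.25, 0.5), function(p) gaps_s[which(cw >= p)[1]], 0)
    sas <- sum(w_s[gaps_s < sas_threshold])
  }
  c(`Q1 MLCGap` = q[1], `Median MLCGap` = q[2], SAS10 = sas)
}

#' @describeIn complexity_metrics Modulation complexity score in (0, 1]:
#'   the meterset-weighted product of aperture-area variability (AAV) and
#'   leaf-sequence variability (LSV); 1 for a static rectangular aperture.
#' @export
mcs <- function(arc, machine = arc$machine,
                g = arc_aperture_stats(arc, machine)) {
  n_cp <- nrow(g$gap)
  gap_o <- g$gap * g$open
  # AAV: per-pair maximum open gap over the arc in the denominator
  gmax <- col_max(gap_o)
  wmax <- col_max(g$width)
  denom <- sum(gmax * wmax)
  aav <- if (denom > 0) rowSums(gap_o * g$width) / denom else rep(1, n_cp)
  lsv_bank <- function(x, open_row) {
    idx <- which(open_row)
    n <- length(idx)
    if (n < 2) return(1)
    xx <- x[idx]
    pos_max <- max(xx) - min(xx)
    if (pos_max <= 0) return(1)
    sum(pos_max - abs(diff(xx))) / ((n - 1) * pos_max)
  }
  lsv <- vapply(seq_len(n_cp), function(k) {
    lsv_bank(arc$bankA[k, ], g$open[k, ]) *
      lsv_bank(arc$bankB[k, ], g$open[k, ])
  }, 0)
  dmu <- diff(arc$cum_weight)
  prod_cp <- aav * lsv
  seg <- (prod_cp[-n_cp] + prod_cp[-1]) / 2
  c(MCS = sum(dmu * seg))
}

#' @describeIn complexity_metrics Mean tongue-and-groove index: exposed
#'   side-edge steps between adjacent open pairs relative to twice the total
#'   open gap, meterset-weighted over control points; 0 for aligned tips.
#' @export
mean_tgi <- function(arc, machine = arc$machine,
                     g = arc_aperture_stats(arc, machine)) {
  defined <- g$gap_sum > 0
  tgi <- ifelse(defined, g$tgi_num / (2 * g$gap_sum), NA)
  dmu <- diff(arc$cum_weight) * arc$total_mu
  c(MeanTGI = mu_weighted_cp_mean(tgi, dmu, keep = defined))
}

#' @describeIn complexity_metrics Total modulation index: area under the
#'   weighted exceedance curve `z(f)` of in-field leaf speeds for
#'   `f in [0, 2]` standard deviations, each (leaf, segment) observation
#'   weighted by `1 + alpha |dDR|/DR_max + beta |dGS|/GS_max`.
#' @param alpha,beta dose-rate and gantry-speed weighting strengths.
#' @param grid_step integration step on the `f` grid.
#' @export
mi_total <- function(dyn, machine, alpha = 1, beta = 1, grid_step = 0.01) {
  infield <- cbind(dyn$open_pair, dyn$open_pair)
  v <- dyn$leaf_speed
  obs_v <- v[infield]
  if (length(obs_v) < 2) return(c(MITotal = 0))
  sigma <- stats::sd(obs_v)
  if (!is.finite(sigma) || sigma <= 0) return(c(MITotal = 0))
  w_seg <- 1 + alpha * c(0, abs(diff(dyn$dose_rate))) / machine$max_dose_rate +
               beta  * c(0, abs(diff(dyn$gantry_speed))) / machine$max_gantry_speed
  wmat <- matrix(w_seg, nrow(v), ncol(v))
  obs_w <- wmat[infield]
  o <- order(obs_v)
  v_s <- obs_v[o]
  cw <- cumsum(obs_w[o])
  total_w <- cw[length(cw)]
  f <- seq(0, 2, by = grid_step)
  # weighted fraction of observations with v > f * sigma
  idx <- findInterval(f * sigma, v_s)          # number of v <= threshold
  z <- (total_w - ifelse(idx == 0, 0, cw[pmax(idx, 1)])) / total_w
  c(MITotal = sum((z[-1] + z[-length(z)]) / 2) * grid_step)
}

#' @describeIn complexity_metrics Beam irregularity `BI` (meterset-weighted
#'   mean of `perimeter^2 / (4 pi area)`, >= 4/pi for rectilinear apertures)
#'   and beam modulation `BM = 1 - sum_k dMU_k A_k / (MU A_union)` where
#'   `A_union` is the area of the union of all apertures of the arc.
#' @export
bi_bm <- function(arc, machine = arc$machine,
                  g = arc_aperture_stats(arc, machine)) {
  if (all(g$area <= 0)) stop("arc has zero aperture area everywhere")
  dmu <- diff(arc$cum_weight) * arc$total_mu
  pos <- g$area > 0
  bi_cp <- ifelse(pos, g$perimeter^2 / (4 * pi * pmax(g$area, 1e-12)), NA)
  bi <- mu_weighted_cp_mean(bi_cp, dmu, keep = pos)
  # per-pair union of open intervals across control points
  a_union <- 0
  for (p in seq_len(machine$n_pairs)) {
    k <- which(g$open[, p])
    if (!length(k)) next
    wp <- g$width[k, p]
    # widths can differ across CPs if jaws move; use max clipped width
    a_union <- a_union +
      interval_union_length(arc$bankA[k, p], arc$bankB[k, p]) * max(wp)
  }
  bm <- 1 - mu_weighted_cp_mean(g$area, dmu) / a_union
  c(BI = bi, BM = bm)
}

#' @describeIn complexity_metrics Edge metric: meterset-weighted mean of the
#'   exposed leaf-side edge length over the aperture area (mm^-1).
#' @export
edge_metric <- function(arc, machine = arc$machine,
                        g = arc_aperture_stats(arc, machine)) {
  if (all(g$area <= 0)) stop("arc has zero aperture area everywhere")
  dmu <- diff(arc$cum_weight) * arc$total_mu
  pos <- g$area > 0
  em_cp <- ifelse(pos, g$side_length / pmax(g$area, 1e-12), NA)
  c(EdgeMetric = mu_weighted_cp_mean(em_cp, dmu, keep = pos))
}

#' @describeIn complexity_metrics Mean in-field leaf travel divided by the
#'   arc length (mm/deg).
#' @export
lt_al <- function(arc, machine = arc$machine,
                  dyn = segment_time_model(arc, machine)) {
  ever_open <- apply(dyn$open_pair, 2, any)
  if (!any(ever_open)) return(c(`LT/AL` = 0))
  travel_per_leaf <- colSums(dyn$leaf_travel)        # mm, 2*n_pairs leaves
  leaves <- c(ever_open, ever_open)
  c(`LT/AL` = mean(travel_per_leaf[leaves]) / dyn$arc_length)
}

#' Table of the 18 feature names in canonical order
#' @return character vector of length 18.
#' @export
feature_names <- function() {
  c("Area", "MUOverDosePerFraction", "MeanMLCSpeed", "MLCSpeedModulation",
    "MeanRR", "RRModulation", "MeanGS", "GSModulation",
    "Q1 MLCGap", "Median MLCGap", "SAS10", "MeanTGI", "MCS", "MITotal",
    "BI", "BM", "EdgeMetric", "LT/AL")
}

# all 18 metrics for one arc, as a named numeric vector
arc_features <- function(arc, machine = arc$machine) {
  dyn <- segment_time_model(arc, machine)
  g <- arc_aperture_stats(arc, machine)
  out <- c(static_metrics(arc, machine, g = g),
           dynamic_metrics(dyn),
           gap_statistics(arc, machine, g = g),
           mean_tgi(arc, machine, g = g),
           mcs(arc, machine, g = g),
           mi_total(dyn, machine),
           bi_bm(arc, machine, g = g),
           edge_metric(arc, machine, g = g),
           lt_al(arc, machine, dyn = dyn))
  out[feature_names()]
}

#' Extract the per-arc feature table from a list of arcs
#'
#' Computes all 18 complexity features for every arc. Arcs for which any
#' metric precondition fails (e.g. a fully closed arc) are excluded from the
#' table and reported in the `failures` attribute.
#'
#' @param arcs list of [arc_beam()] objects.
#' @param machine a [machine_spec()]; defaults to each arc's own machine.
#' @param qa optional QA table (e.g. from [qa_record()] or
#'   [generate_cohort()]) with columns `arc_id` and `measured_gpr`, joined by
#'   `arc_id`.
#' @return a data.frame (one row per arc) with columns `arc_id`,
#'   `treatment_date`, the 18 features (names exactly as documented in
#'   [feature_names()]), and `measured_gpr` when `qa` is given. The attribute
#'   `failures` is a data.frame of excluded arcs and reasons.
#' @export
extract_features <- function(arcs, machine = NULL, qa = NULL) {
  vals <- matrix(NA_real_, length(arcs), 18,
                 dimnames = list(NULL, feature_names()))
  ids <- character(length(arcs))
  dates <- rep(as.Date(NA), length(arcs))
  ok <- logical(length(arcs))
  fails <- list()
  for (i in seq_along(arcs)) {
    arc <- arcs[[i]]
    m <- if (is.null(machine)) arc$machine else machine
    f <- tryCatch(arc_features(arc, m), error = function(e) e)
    if (inherits(f, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(arc_id = arc$arc_id, reason = conditionMessage(f),
                   stringsAsFactors = FALSE)
    } else {
      vals[i, ] <- f
      ids[i] <- arc$arc_id
      dates[i] <- arc$treatment_date
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("no arc yielded a complete feature vector")
  out <- data.frame(arc_id = ids[ok], treatment_date = dates[ok],
                    vals[ok, , drop = FALSE], check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(qa))
    out$measured_gpr <- qa$measured_gpr[match(out$arc_id, qa$arc_id)]
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(arc_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Read or write a feature table as CSV
#'
#' Column names are written exactly as documented in [feature_names()]
#' (including spaces and the `LT/AL` slash).
#'
#' @param table a feature table from [extract_features()].
#' @param path file path.
#' @return `read_feature_table` returns the data.frame with
#'   `treatment_date` restored as `Date`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if ("treatment_date" %in% names(out))
    out$treatment_date <- as.Date(out$treatment_date)
  out
}
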