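#' Synthetic-cohort configuration
#'
#' Describes a synthetic single-isocenter SRS QA cohort: number of patients,
#' per-patient arc-count distribution, treatment date range, complexity-level
#' distribution (with a mild temporal drift so the time-series split is
#' non-exchangeable), and how measured GPRs are simulated. The defaults
#' emulate the scale of a four-year clinical SRS program: 592 patients with
#' 2 to 6 arcs each (mean ~4.10, expected total ~2430 arcs) between
#' 2020-12-01 and 2024-12-31.
#'
#' @param n_patients number of patients.
#' @param arcs_per_patient integer support of the per-patient arc count.
#' @param arc_prob probabilities over `arcs_per_patient`.
#' @param date_range length-2 `Date` vector.
#' @param level_shape1,level_shape2 Beta parameters of the baseline
#'   complexity level (left-skewed by default: most SRS arcs are complex).
#' @param level_drift total linear drift of the mean complexity level over
#'   the date range (late plans slightly more complex).
#' @param mode `"statistical"` (calibrated planted-outcome law, default) or
#'   `"physical"` (fluence + gamma simulation; use small cohorts).
#' @param model a [planted_model()] (statistical mode).
#' @param error_model delivery error model (physical mode), see
#'   [simulate_gpr_physical()].
#' @param seed integer seed; fixed seed gives identical output.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 592,
                          arcs_per_patient = 2:6,
                          arc_prob = c(0.10, 0.22, 0.30, 0.24, 0.14),
                          date_range = as.Date(c("2020-12-01", "2024-12-31")),
                          level_shape1 = 3.5, level_shape2 = 1.8,
                          level_drift = 0.12,
                          mode = c("statistical", "physical"),
                          model = planted_model(),
                          error_model = delivery_error_model(),
                          seed = 0) {
  mode <- match.arg(mode)
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (length(arcs_per_patient) != length(arc_prob) ||
      abs(sum(arc_prob) - 1) > 1e-9)
    stop("arc_prob must be a probability vector over arcs_per_patient")
  if (diff(as.numeric(date_range)) <= 0)
    stop("date_range must be increasing")
  structure(list(n_patients = n_patients,
                 arcs_per_patient = arcs_per_patient, arc_prob = arc_prob,
                 date_range = as.Date(date_range),
                 level_shape1 = level_shape1, level_shape2 = level_shape2,
                 level_drift = level_drift, mode = mode, model = model,
                 error_model = error_model, seed = seed),
            class = "cohort_config")
}

#' Planted complexity-to-GPR model
#'
#' The statistical outcome law: an arc's failure magnitude
#' `d = d_max * plogis(location + score + noise_sd * eps)`,
#' `GPR = 100 (1 - d)` clipped to `[70, 100]`, where the planted score is a
#' linear combination of standardized features (small aperture `Area`, small
#' `Median MLCGap`, high `BM`, high `MITotal` push toward failure) and
#' `eps ~ N(0, 1)`. Feature standardization uses the committed reference
#' moments `ref` (computed once from the default cohort), so a row's GPR
#' depends only on that row and the seed. `location` and `noise_sd` are the
#' two calibration constants fitted by [calibrate_gpr_marginal()] so the
#' default cohort reproduces the target GPR marginal (median 98.3%,
#' Q1-Q3 95.1-99.6%); the committed defaults are the fitted values.
#'
#' @param coef named coefficients on standardized features.
#' @param location,noise_sd calibration constants of the failure law.
#' @param d_max maximum failure magnitude (GPR floor 100 - 100 d_max).
#' @param ref data.frame `feature`, `center`, `scale` of reference moments.
#' @return object of class `planted_model`.
#' @export
planted_model <- function(coef = c(Area = -0.55, `Median MLCGap` = -0.55,
                                   BM = 0.45, MITotal = 0.35),
                          location = -2.4834, noise_sd = 0.918,
                          d_max = 0.20,
                          ref = planted_reference_moments()) {
  stopifnot(all(names(coef) %in% ref$feature))
  structure(list(coef = coef, location = location, noise_sd = noise_sd,
                 d_max = d_max, ref = ref),
            class = "planted_model")
}

#' @rdname planted_model
#' @export
planted_reference_moments <- function() {
  # moments of the default generator at its committed settings (seed-free
  # expectations estimated once from a large calibration cohort)
  data.frame(
    feature = c("Area", "Median MLCGap", "BM", "MITotal"),
    center = c(818.689, 16.9151, 0.43902, 0.69927),
    scale = c(340.637, 5.30725, 0.16214, 0.13062),
    stringsAsFactors = FALSE)
}

#' Sample one synthetic HyperArc-like arc
#'
#' Generates a valid dynamic arc whose modulation depends monotonically on a
#' complexity level in `[0, 1]`: higher level gives smaller mean leaf gaps
#' and aperture area, larger leaf travel and speed modulation. Uses R's
#' random number generator; seed with `set.seed()` for reproducibility.
#'
#' @param level complexity level in `[0, 1]`.
#' @param machine a [machine_spec()].
#' @param arc_id,patient_id,treatment_date identifiers for the new arc.
#' @param n_cp_range integer range of control-point counts.
#' @param arc_len_range arc length range, deg.
#' @return an [arc_beam()] that passes [validate_arc()].
#' @export
sample_arc <- function(level, machine = machine_spec(),
                       arc_id = "A1", patient_id = "P1",
                       treatment_date = as.Date("2022-01-01"),
                       n_cp_range = 80:180, arc_len_range = c(160, 360)) {
  if (level < 0 || level > 1) stop("level must be in [0, 1]")
  n_cp <- if (length(n_cp_range) == 1) n_cp_range else sample(n_cp_range, 1)
  arc_len <- stats::runif(1, arc_len_range[1], arc_len_range[2])
  start <- stats::runif(1, 0, 360)
  dir <- sample(c(-1, 1), 1)
  gantry <- (start + dir * seq(0, arc_len, length.out = n_cp)) %% 360

  np <- machine$n_pairs
  b <- machine$boundaries
  centers_y <- (b[-1] + b[-length(b)]) / 2
  extent <- stats::runif(1, 25, 70)
  c0 <- stats::runif(1, -15, 15)
  active <- which(centers_y > c0 - extent / 2 & centers_y < c0 + extent / 2)
  if (length(active) < 2) active <- (np %/% 2):(np %/% 2 + 1)
  na <- length(active)

  g_base <- max(3, 35 * (1 - 0.72 * level) + stats::rnorm(1, 0, 2))
  # every modulation source ramps to exactly zero at level 0 (full
  # strength by level 0.2): the low-complexity limit is a static
  # rectangular aperture, the only aperture with LSV = 1 and hence
  # MCS ~ 1 (leaf-sequence variability is scale-invariant, so residual
  # tip noise of any size would cap MCS near 0.8)
  ramp <- min(1, 5 * level)
  a_mod <- 0.05 * ramp + 0.60 * level
  # fraction of leaf pairs that actually move grows with complexity;
  # static pairs keep the modulation index low for simple arcs
  p_dyn <- 0.25 * ramp + 0.75 * level
  th <- seq(0, 2 * pi, length.out = n_cp)
  phase <- stats::runif(na, 0, 2 * pi)
  freq <- sample(1:3, na, replace = TRUE)
  smooth_noise <- function(n, span = 9) {
    x <- stats::rnorm(n + span)
    stats::filter(x, rep(1 / span, span), sides = 1)[(span + 1):(n + span)]
  }
  # smooth cross-pair aperture profile (roughly elliptical target) with
  # level-dependent raggedness, so low-complexity arcs have aligned tips
  prof <- seq(-1, 1, length.out = na)
  curve_amp <- (3 + 5 * stats::runif(1)) * ramp
  base_off <- curve_amp * sin(pi * prof / 2 +
                              stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(na, 0, 0.2 * ramp + 6 * level)
  gap_pair <- pmax(2, g_base * (1 - 0.25 * ramp * (0.15 + 0.85 * level) *
                                  prof^2) *
                     (1 + stats::rnorm(na, 0, 0.03 * ramp + 0.25 * level)))
  dyn_pair <- stats::runif(na) < p_dyn
  gap <- matrix(0, n_cp, na)
  shift <- matrix(0, n_cp, na)
  drift_amp <- 1.5 * ramp + 16 * level
  for (j in seq_len(na)) {
    if (dyn_pair[j]) {
      sj <- sin(freq[j] * th + phase[j]) + 1.2 * smooth_noise(n_cp)
      gap[, j] <- pmax(machine$min_gap, gap_pair[j] *
                         (1 + a_mod * sj / max(1e-9, stats::sd(sj)) / 2))
      shift[, j] <- base_off[j] + drift_amp * cumsum(smooth_noise(n_cp)) /
        max(1, sqrt(n_cp))
    } else {
      gap[, j] <- gap_pair[j]
      shift[, j] <- base_off[j]
    }
  }
  center_x <- shift
  bankA <- matrix(0, n_cp, np); bankB <- matrix(0, n_cp, np)
  lim <- machine$field_extent - 1
  A <- pmax(-lim, pmin(lim, center_x - gap / 2))
  B <- pmax(-lim, pmin(lim, center_x + gap / 2))
  B <- pmax(B, A)
  bankA[, active] <- A
  bankB[, active] <- B

  y1 <- b[min(active)]; y2 <- b[max(active) + 1]
  x1 <- max(-lim, min(A) - 5); x2 <- min(lim, max(B) + 5)
  jaws <- c(x1, x2, y1, y2)

  shape <- max(2, 12 - 8 * level)
  inc <- stats::rgamma(n_cp - 1, shape = shape)
  cw <- c(0, cumsum(inc) / sum(inc))
  cw[n_cp] <- 1

  dpf <- sample(c(8, 9, 15, 18, 21, 24), 1,
                prob = c(0.15, 0.15, 0.15, 0.25, 0.20, 0.10))
  mu_per_gy <- max(60, 150 + 250 * level + stats::rnorm(1, 0, 25))
  arc_beam(arc_id = arc_id, patient_id = patient_id,
           treatment_date = treatment_date,
           cum_weight = cw, gantry_angle = gantry,
           bankA = bankA, bankB = bankB, jaws = jaws,
           total_mu = mu_per_gy * dpf, dose_per_fraction = dpf,
           machine = machine)
}

planted_score <- function(features, model) {
  s <- rep(0, nrow(features))
  for (f in names(model$coef)) {
    i <- match(f, model$ref$feature)
    s <- s + model$coef[[f]] *
      (features[[f]] - model$ref$center[i]) / model$ref$scale[i]
  }
  s
}

#' Simulate measured GPR from features (statistical mode)
#'
#' @param features data.frame with at least the planted-model features.
#' @param model a [planted_model()].
#' @return measured GPR, percent, clipped to `[70, 100]`. Uses R's RNG.
#' @export
simulate_gpr_statistical <- function(features, model = planted_model()) {
  s <- planted_score(features, model)
  eta <- model$location + s + model$noise_sd * stats::rnorm(length(s))
  d <- model$d_max * stats::plogis(eta)
  pmax(70, pmin(100, 100 * (1 - d)))
}

#' Delivery error model for the physical GPR simulation
#'
#' @param gap_offset_mm systematic symmetric leaf-gap offset, mm.
#' @param leaf_sd_mm per-leaf, per-control-point position noise, mm.
#' @param output_sd relative output (dose scaling) noise.
#' @return a list of class `delivery_error_model`.
#' @export
delivery_error_model <- function(gap_offset_mm = 0.35, leaf_sd_mm = 0.25,
                                 output_sd = 0.006) {
  structure(list(gap_offset_mm = gap_offset_mm, leaf_sd_mm = leaf_sd_mm,
                 output_sd = output_sd), class = "delivery_error_model")
}

# meterset-weighted aperture fluence on a regular grid, Gaussian penumbra
fluence_image <- function(arc, machine = arc$machine, spacing = 1,
                          sigma = 1.5, margin = 6, extent = NULL) {
  if (is.null(extent)) {
    extent <- c(min(arc$jaws[, "x1"]) - margin, max(arc$jaws[, "x2"]) + margin,
                min(arc$jaws[, "y1"]) - margin, max(arc$jaws[, "y2"]) + margin)
  }
  xs <- seq(extent[1], extent[2], by = spacing)
  ys <- seq(extent[3], extent[4], by = spacing)
  b <- machine$boundaries
  pair_of_y <- findInterval(ys, b, rightmost.closed = TRUE)
  g <- arc_aperture_stats(arc, machine)
  n_cp <- nrow(arc$bankA)
  dmu <- diff(arc$cum_weight)
  cpw <- c(dmu / 2, 0) + c(0, dmu / 2)
  F <- matrix(0, length(ys), length(xs))
  in_jaw_y <- outer(ys, arc$jaws[1, "y1"], ">") &
              outer(ys, arc$jaws[1, "y2"], "<")
  for (k in seq_len(n_cp)) {
    if (cpw[k] <= 0) next
    op <- which(g$open[k, ])
    if (!length(op)) next
    rows <- which(pair_of_y %in% op & ys > arc$jaws[k, "y1"] &
                    ys < arc$jaws[k, "y2"])
    if (!length(rows)) next
    a <- arc$bankA[k, pair_of_y[rows]]
    bb <- arc$bankB[k, pair_of_y[rows]]
    open_cols <- outer(a, xs, "<=") & outer(bb, xs, ">=")
    F[rows, ] <- F[rows, ] + cpw[k] * open_cols
  }
  # separable Gaussian penumbra
  if (sigma > 0) {
    half <- ceiling(3 * sigma / spacing)
    kx <- stats::dnorm(seq(-half, half) * spacing, sd = sigma)
    kx <- kx / sum(kx)
    blur1 <- function(M) {
      out <- matrix(0, nrow(M), ncol(M))
      for (i in seq_along(kx)) {
        sh <- i - half - 1
        src <- pmin(pmax(seq_len(ncol(M)) + sh, 1), ncol(M))
        out <- out + kx[i] * M[, src, drop = FALSE]
      }
      out
    }
    F <- t(blur1(t(blur1(F))))
  }
  dose_image(F * arc$total_mu, pixel_spacing = spacing)
}

#' Simulate measured GPR by fluence comparison (physical mode)
#'
#' Builds a planned fluence image from the arc (meterset-accumulated
#' aperture masks with a Gaussian penumbra) and a delivered image from a
#' perturbed copy (systematic leaf-gap offset, per-leaf noise, output
#' scaling), then runs the gamma engine. Much slower than the statistical
#' mode; intended for small cohorts.
#'
#' @param arc an [arc_beam()].
#' @param error_model a [delivery_error_model()].
#' @param criteria a [gamma_criteria()].
#' @param spacing grid spacing of the synthetic dose images, mm.
#' @return measured GPR, percent. Uses R's RNG.
#' @export
simulate_gpr_physical <- function(arc, error_model = delivery_error_model(),
                                  criteria = gamma_criteria(),
                                  spacing = 1) {
  machine <- arc$machine
  ref <- fluence_image(arc, machine, spacing = spacing)
  pert <- arc
  off <- error_model$gap_offset_mm / 2
  noiseA <- matrix(stats::rnorm(length(arc$bankA), 0, error_model$leaf_sd_mm),
                   nrow(arc$bankA))
  noiseB <- matrix(stats::rnorm(length(arc$bankB), 0, error_model$leaf_sd_mm),
                   nrow(arc$bankB))
  open <- open_pairs(arc, machine)
  pert$bankA <- arc$bankA - (off + noiseA * 0.5) * open
  pert$bankB <- arc$bankB + (off + noiseB * 0.5) * open
  pert$bankB <- pmax(pert$bankB, pert$bankA)
  ev <- fluence_image(pert, machine, spacing = spacing,
                      extent = attr_extent(ref, arc, spacing))
  scale <- 1 + stats::rnorm(1, 0, error_model$output_sd)
  ev$values <- ev$values * scale    # pmax(0, .) would drop the dim
  ev$values[ev$values < 0] <- 0
  if (!identical(dim(ev$values), dim(ref$values)))
    stop("internal: fluence grids diverged")
  passing_rate(gamma_map(ref, ev, criteria), ref, criteria)
}

attr_extent <- function(ref, arc, spacing) {
  margin <- 6
  c(min(arc$jaws[, "x1"]) - margin, max(arc$jaws[, "x2"]) + margin,
    min(arc$jaws[, "y1"]) - margin, max(arc$jaws[, "y2"]) + margin)
}

#' Generate a synthetic QA cohort
#'
#' Patients are assigned consecutive blocks of the date range (all arcs of a
#' patient share its date); each patient draws an arc count and each arc a
#' complexity level from the (drifting) level distribution; measured GPRs
#' are simulated in the configured mode. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param machine a [machine_spec()].
#' @param keep_arcs keep the `arc_beam` objects in the result (set FALSE to
#'   save memory when only the feature table is needed).
#' @return list of class `qa_cohort`: `arcs` (list or NULL), `features`
#'   (data.frame incl. `measured_gpr`), `qa` (arc_id, treatment_date,
#'   measured_gpr, pass_label), `levels`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            machine = machine_spec(),
                            keep_arcs = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  n_pat <- config$n_patients
  n_arcs <- sample(config$arcs_per_patient, n_pat, replace = TRUE,
                   prob = config$arc_prob)
  t_frac <- if (n_pat > 1) (seq_len(n_pat) - 1) / (n_pat - 1) else 0.5
  dates <- config$date_range[1] +
    round(t_frac * diff(as.numeric(config$date_range)))
  arcs <- vector("list", sum(n_arcs))
  levels <- numeric(sum(n_arcs))
  idx <- 0L
  for (p in seq_len(n_pat)) {
    pid <- sprintf("P%04d", p)
    for (a in seq_len(n_arcs[p])) {
      idx <- idx + 1L
      base <- stats::rbeta(1, config$level_shape1, config$level_shape2)
      lv <- min(1, max(0, base + config$level_drift * (t_frac[p] - 0.5)))
      levels[idx] <- lv
      arcs[[idx]] <- sample_arc(lv, machine,
                                arc_id = sprintf("%s_A%d", pid, a),
                                patient_id = pid, treatment_date = dates[p])
    }
  }
  features <- extract_features(arcs, machine)
  gpr <- if (config$mode == "statistical") {
    simulate_gpr_statistical(features, config$model)
  } else {
    vapply(arcs[match(features$arc_id,
                      vapply(arcs, function(x) x$arc_id, ""))],
           simulate_gpr_physical, 0,
           error_model = config$error_model)
  }
  features$measured_gpr <- gpr
  qa <- data.frame(arc_id = features$arc_id,
                   treatment_date = features$treatment_date,
                   measured_gpr = gpr,
                   pass_label = gpr >= 95,
                   stringsAsFactors = FALSE)
  structure(list(arcs = if (keep_arcs) arcs else NULL,
                 features = features, qa = qa, levels = levels,
                 config = config),
            class = "qa_cohort")
}

#' Calibrate the failure-law constants against target GPR quantiles
#'
#' Fits the two constants of [planted_model()] (`location`, `noise_sd`) by
#' nested bisection so the simulated marginal GPR of the default cohort
#' matches target quantiles (median and interquartile range). The planted
#' scores and noise draws are generated once from default-configured
#' cohorts, then the constants are solved on that fixed sample; the fitted
#' values are committed as the `planted_model()` defaults.
#'
#' @param target named vector `median`, `q1`, `q3` of the target marginal, %.
#' @param seeds cohort seeds used for the score sample.
#' @param model starting [planted_model()].
#' @param config base [cohort_config()].
#' @return list `location`, `noise_sd`, `achieved` (quantiles).
#' @export
calibrate_gpr_marginal <- function(target = c(median = 98.3, q1 = 95.1,
                                              q3 = 99.6),
                                   seeds = 0:2,
                                   model = planted_model(),
                                   config = cohort_config()) {
  scores <- unlist(lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    co <- generate_cohort(cfg, keep_arcs = FALSE)
    planted_score(co$features, model)
  }))
  set.seed(12345)
  eps <- stats::rnorm(length(scores))
  quants <- function(location, noise_sd) {
    d <- model$d_max * stats::plogis(location + scores + noise_sd * eps)
    g <- pmax(70, pmin(100, 100 * (1 - d)))
    stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  }
  solve_loc <- function(noise_sd) {
    lo <- -8; hi <- 0
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (quants(mid, noise_sd)[2] > target[["median"]]) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  target_iqr <- target[["q3"]] - target[["q1"]]
  lo <- 0.05; hi <- 4
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    loc <- solve_loc(mid)
    q <- quants(loc, mid)
    if (q[3] - q[1] < target_iqr) lo <- mid else hi <- mid
  }
  noise_sd <- (lo + hi) / 2
  location <- solve_loc(noise_sd)
  list(location = location, noise_sd = noise_sd,
       achieved = quants(location, noise_sd))
}
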