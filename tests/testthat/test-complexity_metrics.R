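test_that("aperture geometry matches closed forms on rectangles", {
  m <- toy_machine(n_pairs = 4, width = 2.5)
  cp <- list(bankA = c(0, -5, 0, 0), bankB = c(0, 5, 0, 0),
             jaws = c(-100, 100, -5, 5))
  ap <- aperture_geometry(cp, m)
  expect_equal(ap$area, 25)                       # 10 mm gap x 2.5 mm width
  expect_equal(ap$perimeter, 2 * 10 + 2 * 2.5)
  expect_equal(ap$side_length, 2 * 10)            # top + bottom edges
  expect_equal(sum(ap$open), 1)

  closed <- list(bankA = rep(0, 4), bankB = rep(0, 4),
                 jaws = c(-100, 100, -5, 5))
  ap0 <- aperture_geometry(closed, m)
  expect_equal(ap0$area, 0)
  expect_length(ap0$open_gaps, 0)
})

test_that("aperture geometry matches the rasterization oracle", {
  set.seed(101)
  for (rep in 1:12) {
    arc <- random_small_arc()
    g <- arcqa:::arc_aperture_stats(arc)
    k <- sample(nrow(arc$bankA), 1)
    mask <- oracle_raster(arc, k, step = 0.1)
    expect_equal(g$area[k], oracle_raster_area(mask), tolerance = 0.02)
    if (g$area[k] > 0) {
      expect_equal(g$perimeter[k], oracle_raster_perimeter(mask),
                   tolerance = 0.02)
      expect_equal(g$side_length[k], oracle_raster_side(mask),
                   tolerance = 0.02)
    }
  }
})

test_that("segment time model reproduces the constraint maxima", {
  m <- toy_machine(n_pairs = 2, max_dose_rate = 1400, max_gantry_speed = 4.8)
  # MU-limited: dMU 10, dGantry 2 deg, no leaf motion
  arc <- toy_arc(bankA = rbind(c(-10, 0), c(-10, 0)),
                 bankB = rbind(c(10, 0), c(10, 0)),
                 cum_weight = c(0, 1), gantry = c(180, 182), total_mu = 10,
                 machine = m)
  dyn <- segment_time_model(arc, m)
  expect_equal(dyn$duration, max(10 / 1400 * 60, 2 / 4.8), tolerance = 1e-9)
  expect_equal(dyn$duration, 0.42857143, tolerance = 1e-6)
  expect_equal(dyn$dose_rate, 1400, tolerance = 1e-9)

  # gantry-limited: dMU 1, dGantry 4.8 deg -> 1 s, 60 MU/min, 4.8 deg/s
  arc2 <- toy_arc(bankA = rbind(c(-10, 0), c(-10, 0)),
                  bankB = rbind(c(10, 0), c(10, 0)),
                  cum_weight = c(0, 1), gantry = c(180, 184.8), total_mu = 1,
                  machine = m)
  dyn2 <- segment_time_model(arc2, m)
  expect_equal(dyn2$duration, 1)
  expect_equal(dyn2$dose_rate, 60)
  expect_equal(dyn2$gantry_speed, 4.8)

  # zero-motion zero-MU segment errors
  arc3 <- toy_arc(bankA = rbind(c(-10, 0), c(-10, 0), c(-10, 0)),
                  bankB = rbind(c(10, 0), c(10, 0), c(10, 0)),
                  cum_weight = c(0, 1, 1), gantry = c(180, 184, 184),
                  machine = m)
  expect_error(segment_time_model(arc3, m), "zero-duration")

  # random arcs: durations equal the scalar-loop oracle
  set.seed(102)
  for (rep in 1:10) {
    arc <- random_small_arc()
    expect_equal(segment_time_model(arc)$duration,
                 oracle_segment_times(arc), tolerance = 1e-12)
  }
})

test_that("static metrics: weighted area and MU per Gy", {
  a <- rect_arc(gap = 10, open_idx = 2:3, total_mu = 4800,
                dose_per_fraction = 24)
  s <- static_metrics(a)
  expect_equal(unname(s["Area"]), 10 * 5 * 2)     # constant field
  expect_equal(unname(s["MUOverDosePerFraction"]), 200)

  # 3-CP arc, per-CP areas 10/10/30 mm2 via single pair widths 5,
  # meterset increments 0.25 / 0.75: segment attribution gives
  # 0.25*(10+10)/2 + 0.75*(10+30)/2 = 17.5
  m <- toy_machine(n_pairs = 2)
  arc <- toy_arc(bankA = rbind(c(-1, 0), c(-1, 0), c(-3, 0)),
                 bankB = rbind(c(1, 0), c(1, 0), c(3, 0)),
                 cum_weight = c(0, 0.25, 1), machine = m)
  expect_equal(unname(static_metrics(arc)["Area"]), 17.5)
})

test_that("dynamic metrics match closed forms and the loop oracle", {
  # constant dose rate and gantry speed: modulations vanish
  a <- rect_arc(n_cp = 6)
  d <- dynamic_metrics(segment_time_model(a))
  expect_equal(unname(d["RRModulation"]), 0)
  expect_equal(unname(d["GSModulation"]), 0)
  expect_equal(unname(d["MLCSpeedModulation"]), 0)
  expect_equal(unname(d["MeanMLCSpeed"]), 0)

  # DR sequence (600, 1400, 600) MU/min over a 120 deg arc
  dyn <- structure(list(duration = c(1, 1, 1), dose_rate = c(600, 1400, 600),
                        gantry_speed = c(4, 4, 4), delta_gantry = c(40, 40, 40),
                        leaf_speed = matrix(0, 3, 4),
                        leaf_travel = matrix(0, 3, 4),
                        open_pair = matrix(TRUE, 3, 2),
                        arc_length = 120, total_mu = 43.33),
                   class = "segment_dynamics")
  expect_equal(unname(dynamic_metrics(dyn)["RRModulation"]), 1600 / 120)

  set.seed(103)
  for (rep in 1:10) {
    arc <- random_small_arc()
    got <- dynamic_metrics(segment_time_model(arc))
    want <- oracle_dynamic(arc)
    for (nm in names(got))
      expect_equal(unname(got[nm]), want[[nm]], tolerance = 1e-12,
                   label = nm)
  }
})

test_that("gap statistics: quantiles, SAS10, and the sort oracle", {
  a <- rect_arc(gap = 5, open_idx = 2:4)
  gs <- gap_statistics(a)
  expect_equal(unname(gs["Q1 MLCGap"]), 5)
  expect_equal(unname(gs["Median MLCGap"]), 5)
  expect_equal(unname(gs["SAS10"]), 1)

  # gaps {4, 8, 12, 16} pooled -> SAS10 = 0.5
  m <- toy_machine(n_pairs = 6)
  bankA <- rbind(c(0, -2, -4, -6, -8, 0), c(0, -2, -4, -6, -8, 0))
  bankB <- rbind(c(0, 2, 4, 6, 8, 0), c(0, 2, 4, 6, 8, 0))
  arc <- toy_arc(bankA, bankB, machine = m)
  expect_equal(unname(gap_statistics(arc)["SAS10"]), 0.5)

  expect_error(gap_statistics(rect_arc(gap = 0.2)), "no open")

  set.seed(104)
  for (rep in 1:10) {
    arc <- random_small_arc()
    gaps <- c()
    for (k in seq_len(nrow(arc$bankA))) for (p in seq_len(ncol(arc$bankA)))
      if (oracle_open(arc, k, p))
        gaps <- c(gaps, arc$bankB[k, p] - arc$bankA[k, p])
    got <- gap_statistics(arc)
    expect_equal(unname(got["Q1 MLCGap"]), oracle_percentile(gaps, 0.25))
    expect_equal(unname(got["Median MLCGap"]), oracle_percentile(gaps, 0.5))
    expect_equal(unname(got["SAS10"]), mean(gaps < 10))
  }
})

test_that("MCS: unmodulated limit, bounds, hand-worked toy, oracle", {
  a <- rect_arc()
  expect_equal(unname(mcs(a)), 1)

  # hand computation: 2 pairs, 3 CPs, cw (0, .5, 1)
  # AAV = (1, .75, .5); LSV = (1, 0, 1); MCS = .5*(1+0)/2 + .5*(0+.5)/2
  m <- toy_machine(n_pairs = 2)
  arc <- toy_arc(bankA = rbind(c(-10, -10), c(-5, -10), c(-5, -5)),
                 bankB = rbind(c(10, 10), c(5, 10), c(5, 5)),
                 cum_weight = c(0, 0.5, 1), machine = m)
  expect_equal(unname(mcs(arc)), 0.375)

  set.seed(105)
  for (rep in 1:10) {
    arc <- random_small_arc()
    v <- unname(mcs(arc))
    expect_gt(v, 0); expect_lte(v, 1)
    expect_equal(v, oracle_mcs(arc), tolerance = 1e-12)
  }
})

test_that("tongue-and-groove index: closed forms and loop oracle", {
  expect_equal(unname(mean_tgi(rect_arc())), 0)   # aligned tips

  # two adjacent pairs, tips offset 5 mm on each bank, gaps 10 mm
  m <- toy_machine(n_pairs = 2)
  arc <- toy_arc(bankA = rbind(c(-5, 0), c(-5, 0)),
                 bankB = rbind(c(5, 10), c(5, 10)),
                 cum_weight = c(0, 1), machine = m)
  expect_equal(unname(mean_tgi(arc)), (5 + 5) / (2 * 20))

  set.seed(106)
  for (rep in 1:10) {
    arc <- random_small_arc()
    cps <- vapply(seq_len(nrow(arc$bankA)), function(k)
      oracle_tgi_cp(arc, k), 0)
    expect_equal(unname(mean_tgi(arc)),
                 oracle_mu_mean(cps, arc$cum_weight), tolerance = 1e-12)
  }
})

test_that("modulation index: conventions and fine-grid oracle", {
  # all leaves static -> 0
  a <- rect_arc(n_cp = 4)
  expect_equal(unname(mi_total(segment_time_model(a), a$machine)), 0)

  # constant nonzero speeds (sigma = 0) -> 0: one pair sweeping uniformly
  m <- toy_machine(n_pairs = 2)
  bankA <- cbind(seq(-30, -10, by = 10), rep(0, 3))
  bankB <- cbind(seq(-10, 10, by = 10), rep(0, 3))
  arc <- toy_arc(bankA, bankB, cum_weight = c(0, 0.5, 1),
                 gantry = c(100, 110, 120), machine = m)
  expect_equal(unname(mi_total(segment_time_model(arc), m)), 0)

  # trapezoid on the fixed 0.01 grid vs a 10x finer oracle grid: z is a
  # step function with jumps ~ 1/n_obs, so the error bound is
  # (0.01/2) * total variation <= 5e-3 for small arcs
  set.seed(107)
  diffs <- vapply(1:10, function(rep) {
    arc <- random_small_arc()
    got <- unname(mi_total(segment_time_model(arc), arc$machine))
    abs(got - oracle_mi(arc))
  }, 0)
  expect_lt(max(diffs), 5e-3)
})

test_that("BI and BM: closed forms and the union oracle", {
  # square aperture: one 5 mm pair open with a 5 mm gap
  m <- toy_machine(n_pairs = 3)
  sq <- toy_arc(bankA = rbind(c(0, -2.5, 0), c(0, -2.5, 0)),
                bankB = rbind(c(0, 2.5, 0), c(0, 2.5, 0)),
                cum_weight = c(0, 1), machine = m)
  expect_equal(unname(bi_bm(sq)["BI"]), 4 / pi, tolerance = 1e-12)
  expect_equal(unname(bi_bm(sq)["BM"]), 0)        # static -> union = field

  # two disjoint equal apertures alternating with equal MU -> BM = 0.5.
  # per-CP apertures [-20,-10] and [10,20] on the same pair never overlap
  arc <- toy_arc(bankA = rbind(c(0, -20, 0), c(0, 10, 0)),
                 bankB = rbind(c(0, -10, 0), c(0, 20, 0)),
                 cum_weight = c(0, 1), machine = m)
  expect_equal(unname(bi_bm(arc)["BM"]), 0.5)

  expect_error(bi_bm(rect_arc(gap = 0.1)), "zero aperture")

  set.seed(108)
  for (rep in 1:8) {
    arc <- random_small_arc()
    expect_equal(unname(bi_bm(arc)["BM"]), oracle_bm(arc), tolerance = 0.02)
    expect_gte(unname(bi_bm(arc)["BI"]), 4 / pi - 1e-9)
  }
})

test_that("edge metric: closed form, monotonicity, raster oracle", {
  # aligned 4-pair rectangle, height H = 20, width W = 30 -> 2/H
  a <- rect_arc(n_cp = 3, n_pairs = 6, open_idx = 2:5, gap = 30)
  expect_equal(unname(edge_metric(a)), 2 / 20, tolerance = 1e-12)

  # comb (alternating open/closed pairs) beats the rectangle of equal area
  m <- toy_machine(n_pairs = 8)
  comb_idx <- c(2, 4, 6)
  comb <- rect_arc(n_cp = 3, n_pairs = 8, open_idx = comb_idx, gap = 30,
                   machine = m)
  rect <- rect_arc(n_cp = 3, n_pairs = 8, open_idx = 2:4, gap = 30,
                   machine = m)
  expect_gt(unname(edge_metric(comb)), unname(edge_metric(rect)))

  set.seed(109)
  for (rep in 1:8) {
    arc <- random_small_arc()
    g <- arcqa:::arc_aperture_stats(arc)
    k <- sample(nrow(arc$bankA), 1)
    if (g$area[k] <= 0) next
    mask <- oracle_raster(arc, k, step = 0.1)
    expect_equal(g$side_length[k] / g$area[k],
                 oracle_raster_side(mask) / oracle_raster_area(mask),
                 tolerance = 0.02)
  }
})

test_that("leaf travel per arc length: closed forms and loop oracle", {
  expect_equal(unname(lt_al(rect_arc())), 0)

  # one leaf travelling 60 mm over a 120 deg arc; 2 open pairs = 4 leaves
  m <- toy_machine(n_pairs = 4)
  bankA <- rbind(c(0, -10, -40, 0), c(0, -10, -10, 0), c(0, -10, 20, 0))
  bankB <- rbind(c(0, 10, 45, 0), c(0, 10, 45, 0), c(0, 10, 45, 0))
  arc <- toy_arc(bankA, bankB, gantry = c(100, 160, 220), machine = m)
  expect_equal(unname(lt_al(arc)), (60 / 4) / 120)

  set.seed(110)
  for (rep in 1:10) {
    arc <- random_small_arc()
    d <- oracle_dynamic(arc)
    ever <- apply(matrix(d$infield[, seq_len(ncol(arc$bankA))],
                         nrow(d$infield)), 2, any)
    np <- ncol(arc$bankA)
    travel <- colSums(matrix(abs(diff(arc$bankA)), ncol = np))
    travel2 <- colSums(matrix(abs(diff(arc$bankB)), ncol = np))
    want <- mean(c(travel[ever], travel2[ever])) / d$arc_length
    expect_equal(unname(lt_al(arc)), want, tolerance = 1e-12)
  }
})

test_that("unmodulated limit: all modulation metrics vanish at once", {
  a <- rect_arc(n_cp = 8, gap = 25)
  f <- arcqa:::arc_features(a)
  expect_equal(unname(f["MCS"]), 1)
  expect_equal(unname(f["BM"]), 0)
  expect_equal(unname(f["MeanTGI"]), 0)
  expect_equal(unname(f["MLCSpeedModulation"]), 0)
  expect_equal(unname(f["RRModulation"]), 0)
  expect_equal(unname(f["GSModulation"]), 0)
  expect_equal(unname(f["MITotal"]), 0)
})

test_that("scaling and reversal properties", {
  set.seed(111)
  for (rep in 1:5) {
    arc <- random_small_arc()
    # doubling all gaps about their centers doubles median gap, not SAS10 up
    arc2 <- arc
    ctr <- (arc$bankA + arc$bankB) / 2
    arc2$bankA <- ctr - (arc$bankB - arc$bankA)
    arc2$bankB <- ctr + (arc$bankB - arc$bankA)
    ext <- arc$machine$field_extent
    arc2$bankA <- pmin(pmax(arc2$bankA, -ext), ext)
    arc2$bankB <- pmin(pmax(arc2$bankB, -ext), ext)
    g1 <- gap_statistics(arc); g2 <- gap_statistics(arc2)
    expect_equal(unname(g2["Median MLCGap"]), 2 * unname(g1["Median MLCGap"]),
                 tolerance = 0.05)
    expect_lte(unname(g2["SAS10"]), unname(g1["SAS10"]))

    # reversing control-point order leaves the metrics unchanged
    rev_arc <- arc
    n <- nrow(arc$bankA)
    rev_arc$bankA <- arc$bankA[n:1, , drop = FALSE]
    rev_arc$bankB <- arc$bankB[n:1, , drop = FALSE]
    rev_arc$jaws <- arc$jaws[n:1, , drop = FALSE]
    rev_arc$gantry_angle <- rev(arc$gantry_angle)
    rev_arc$cum_weight <- 1 - rev(arc$cum_weight)
    f1 <- arcqa:::arc_features(arc)
    f2 <- arcqa:::arc_features(rev_arc)
    # MITotal pairs segment weights with inter-segment dose-rate/gantry
    # differences, so exact reversal invariance holds only for symmetric
    # arcs; all other metrics must be invariant for any arc
    keep <- setdiff(feature_names(), "MITotal")
    expect_equal(f1[keep], f2[keep], tolerance = 1e-9)

    # symmetric (palindromic) arc: every metric, MITotal included
    n <- nrow(arc$bankA)
    sym <- arc
    sym$bankA <- rbind(arc$bankA, arc$bankA[(n - 1):1, , drop = FALSE])
    sym$bankB <- rbind(arc$bankB, arc$bankB[(n - 1):1, , drop = FALSE])
    sym$jaws <- rbind(arc$jaws, arc$jaws[(n - 1):1, , drop = FALSE])
    inc <- diff(arc$cum_weight)
    sym$cum_weight <- c(0, cumsum(c(inc, rev(inc)))) / (2 * sum(inc))
    sym$cum_weight[length(sym$cum_weight)] <- 1
    dg <- diff(arc$gantry_angle)
    sym$gantry_angle <- cumsum(c(arc$gantry_angle[1], dg, rev(dg)))
    rev_sym <- sym
    m2 <- nrow(sym$bankA)
    rev_sym$bankA <- sym$bankA[m2:1, , drop = FALSE]
    rev_sym$bankB <- sym$bankB[m2:1, , drop = FALSE]
    rev_sym$jaws <- sym$jaws[m2:1, , drop = FALSE]
    rev_sym$gantry_angle <- rev(sym$gantry_angle)
    rev_sym$cum_weight <- 1 - rev(sym$cum_weight)
    expect_equal(arcqa:::arc_features(sym), arcqa:::arc_features(rev_sym),
                 tolerance = 1e-9)
  }
})

test_that("every metric matches its oracle on 100 random small arcs", {
  set.seed(999)
  for (rep in 1:100) {
    arc <- random_small_arc()
    f <- arcqa:::arc_features(arc)
    d <- oracle_dynamic(arc)
    expect_equal(unname(f["MeanRR"]), d$MeanRR, tolerance = 1e-10)
    expect_equal(unname(f["MeanGS"]), d$MeanGS, tolerance = 1e-10)
    expect_equal(unname(f["MeanMLCSpeed"]), d$MeanMLCSpeed, tolerance = 1e-10)
    expect_equal(unname(f["MLCSpeedModulation"]), d$MLCSpeedModulation,
                 tolerance = 1e-10)
    expect_equal(unname(f["RRModulation"]), d$RRModulation, tolerance = 1e-10)
    expect_equal(unname(f["GSModulation"]), d$GSModulation, tolerance = 1e-10)
    expect_equal(unname(f["MCS"]), oracle_mcs(arc), tolerance = 1e-10)
    expect_equal(unname(f["BM"]), oracle_bm(arc), tolerance = 0.02)
    cps <- vapply(seq_len(nrow(arc$bankA)), function(k)
      oracle_tgi_cp(arc, k), 0)
    expect_equal(unname(f["MeanTGI"]), oracle_mu_mean(cps, arc$cum_weight),
                 tolerance = 1e-10)
    # invariant bounds
    expect_gt(unname(f["MCS"]), 0); expect_lte(unname(f["MCS"]), 1)
    expect_gte(unname(f["SAS10"]), 0); expect_lte(unname(f["SAS10"]), 1)
    expect_gte(unname(f["BM"]), 0); expect_lte(unname(f["BM"]), 1)
    expect_gte(unname(f["BI"]), 4 / pi - 1e-9)
  }
})

test_that("extract_features routes failures and completes tables", {
  set.seed(112)
  arcs <- lapply(1:10, function(i) {
    a <- sample_arc(runif(1), arc_id = paste0("A", i))
    a
  })
  tab <- extract_features(arcs)
  expect_equal(nrow(tab), 10)
  expect_true(all(feature_names() %in% names(tab)))
  expect_false(anyNA(tab[, feature_names()]))

  # an arc violating the gap_statistics precondition is excluded and logged
  bad <- rect_arc(gap = 0.1)    # fully closed
  bad$arc_id <- "BAD"
  tab2 <- extract_features(c(arcs, list(bad)))
  expect_equal(nrow(tab2), 10)
  fails <- attr(tab2, "failures")
  expect_equal(fails$arc_id, "BAD")
  expect_match(fails$reason, "open")
})
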