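# Independent brute-force oracles. Deliberately written as plain scalar
# loops / rasterizations so they share no code path with the package.

# rasterized aperture mask at `step` mm for one control point
oracle_raster <- function(arc, k, machine = arc$machine, step = 0.1) {
  b <- machine$boundaries
  xs <- seq(-machine$field_extent, machine$field_extent, by = step) + step / 2
  ys <- seq(min(b), max(b), by = step) + step / 2
  ys <- ys[ys < max(b)]
  inside <- matrix(FALSE, length(ys), length(xs))
  for (p in seq_len(machine$n_pairs)) {
    gapp <- arc$bankB[k, p] - arc$bankA[k, p]
    lo <- max(b[p], arc$jaws[k, "y1"]); hi <- min(b[p + 1], arc$jaws[k, "y2"])
    if (gapp <= machine$min_gap || hi <= lo) next
    rows <- which(ys > lo & ys < hi)
    cols <- which(xs > arc$bankA[k, p] & xs < arc$bankB[k, p])
    inside[rows, cols] <- TRUE
  }
  inside
}

oracle_raster_area <- function(mask, step = 0.1) sum(mask) * step^2

# perimeter = count of exposed cell faces x step
oracle_raster_perimeter <- function(mask, step = 0.1) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  faces <- 0
  for (i in 2:(nr + 1)) for (j in 2:(nc + 1)) {
    if (!pad[i, j]) next
    faces <- faces + (!pad[i - 1, j]) + (!pad[i + 1, j]) +
      (!pad[i, j - 1]) + (!pad[i, j + 1])
  }
  faces * step
}

# horizontal (leaf-side) exposed faces only
oracle_raster_side <- function(mask, step = 0.1) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  faces <- 0
  for (i in 2:(nr + 1)) for (j in 2:(nc + 1)) {
    if (!pad[i, j]) next
    faces <- faces + (!pad[i - 1, j]) + (!pad[i + 1, j])
  }
  faces * step
}

# scalar-loop re-implementation of the segment time model
oracle_segment_times <- function(arc, machine = arc$machine) {
  n <- length(arc$cum_weight)
  t <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    dmu <- (arc$cum_weight[k + 1] - arc$cum_weight[k]) * arc$total_mu
    dg <- (arc$gantry_angle[k + 1] - arc$gantry_angle[k]) %% 360
    if (dg > 180) dg <- dg - 360
    travel <- 0
    for (p in seq_len(ncol(arc$bankA))) {
      travel <- max(travel, abs(arc$bankA[k + 1, p] - arc$bankA[k, p]),
                    abs(arc$bankB[k + 1, p] - arc$bankB[k, p]))
    }
    t[k] <- max(dmu / machine$max_dose_rate * 60,
                abs(dg) / machine$max_gantry_speed,
                travel / (10 * machine$max_leaf_speed))
  }
  t
}

# open-pair test identical in wording to the documented closed-pair rule
oracle_open <- function(arc, k, p, machine = arc$machine) {
  b <- machine$boundaries
  gapp <- arc$bankB[k, p] - arc$bankA[k, p]
  gapp > machine$min_gap &&
    b[p + 1] > arc$jaws[k, "y1"] && b[p] < arc$jaws[k, "y2"]
}

# pooled-gap percentile via the textbook linear-interpolation formula
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# scalar loop for the six dynamic metrics
oracle_dynamic <- function(arc, machine = arc$machine) {
  t <- oracle_segment_times(arc, machine)
  n <- length(arc$cum_weight)
  np <- ncol(arc$bankA)
  dr <- gs <- numeric(n - 1)
  al <- 0
  for (k in seq_len(n - 1)) {
    dmu <- (arc$cum_weight[k + 1] - arc$cum_weight[k]) * arc$total_mu
    dg <- (arc$gantry_angle[k + 1] - arc$gantry_angle[k]) %% 360
    if (dg > 180) dg <- dg - 360
    dr[k] <- dmu / t[k] * 60
    gs[k] <- abs(dg) / t[k]
    al <- al + abs(dg)
  }
  v <- matrix(0, n - 1, 2 * np); infield <- matrix(FALSE, n - 1, 2 * np)
  travel <- matrix(0, n - 1, 2 * np)
  for (k in seq_len(n - 1)) for (p in seq_len(np)) {
    open <- oracle_open(arc, k, p) || oracle_open(arc, k + 1, p)
    for (bank in 1:2) {
      pos <- if (bank == 1) arc$bankA else arc$bankB
      j <- (bank - 1) * np + p
      travel[k, j] <- abs(pos[k + 1, p] - pos[k, p])
      v[k, j] <- travel[k, j] / t[k] / 10
      infield[k, j] <- open
    }
  }
  sum_dv <- 0
  for (j in seq_len(2 * np)) for (k in seq_len(n - 2))
    if (infield[k, j] && infield[k + 1, j])
      sum_dv <- sum_dv + abs(v[k + 1, j] - v[k, j])
  list(MeanMLCSpeed = mean(v[infield]),
       MLCSpeedModulation = sum_dv / sum(travel[infield]),
       MeanRR = arc$total_mu / sum(t) * 60,
       RRModulation = sum(abs(diff(dr))) / al,
       MeanGS = al / sum(t),
       GSModulation = sum(abs(diff(gs))) / al,
       infield = infield, v = v, t = t, dr = dr, gs = gs,
       arc_length = al)
}

# scalar loop tongue-and-groove index per CP
oracle_tgi_cp <- function(arc, k, machine = arc$machine) {
  np <- ncol(arc$bankA)
  num <- 0; den <- 0
  for (p in seq_len(np)) {
    if (oracle_open(arc, k, p, machine))
      den <- den + (arc$bankB[k, p] - arc$bankA[k, p])
    if (p < np && oracle_open(arc, k, p, machine) &&
        oracle_open(arc, k, p + 1, machine)) {
      num <- num + abs(arc$bankA[k, p] - arc$bankA[k, p + 1]) +
        abs(arc$bankB[k, p] - arc$bankB[k, p + 1])
    }
  }
  if (den == 0) return(NA_real_)
  num / (2 * den)
}

# segment-attributed meterset-weighted mean of per-CP values
oracle_mu_mean <- function(vals, cw, mu = 1) {
  n <- length(vals)
  num <- 0; den <- 0
  for (k in seq_len(n - 1)) {
    a <- vals[k]; b <- vals[k + 1]
    seg <- if (!is.na(a) && !is.na(b)) (a + b) / 2 else if (!is.na(a)) a
      else if (!is.na(b)) b else NA
    if (is.na(seg)) next
    w <- (cw[k + 1] - cw[k]) * mu
    num <- num + w * seg; den <- den + w
  }
  num / den
}

# weighted exceedance-integral (modulation index) on an explicit fine grid
oracle_mi <- function(arc, machine = arc$machine, f_step = 0.001) {
  d <- oracle_dynamic(arc, machine)
  obs_v <- d$v[d$infield]
  sigma <- sd(obs_v)
  if (!is.finite(sigma) || sigma == 0) return(0)
  wk <- 1 + c(0, abs(diff(d$dr))) / machine$max_dose_rate +
    c(0, abs(diff(d$gs))) / machine$max_gantry_speed
  wobs <- matrix(rep(wk, 2 * ncol(arc$bankA)), nrow = length(wk))[d$infield]
  fs <- seq(0, 2, by = f_step)
  z <- vapply(fs, function(f) sum(wobs[obs_v > f * sigma]) / sum(wobs), 0)
  sum((z[-1] + z[-length(z)]) / 2) * f_step
}

# exhaustive-search 2D gamma on small grids (no early termination)
oracle_gamma <- function(ref, ev, spacing, dose_diff_frac_of_max, dta,
                        radius, upsample) {
  dmax <- max(ref)
  tol <- dose_diff_frac_of_max * dmax
  nr <- nrow(ref); nc <- ncol(ref)
  step <- spacing / upsample
  ks <- seq(-floor(radius / step), floor(radius / step))
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- Inf
    for (a in ks) for (b in ks) {
      dx <- a * step; dy <- b * step
      if (dx^2 + dy^2 > radius^2 + 1e-12) next
      pi_ <- i - 1 + dx / spacing; pj <- j - 1 + dy / spacing
      if (pi_ < 0 || pj < 0 || pi_ > nr - 1 || pj > nc - 1) next
      i0 <- floor(pi_); j0 <- floor(pj)
      i1 <- min(i0 + 1, nr - 1); j1 <- min(j0 + 1, nc - 1)
      fi <- pi_ - i0; fj <- pj - j0
      de <- (1 - fi) * (1 - fj) * ev[i0 + 1, j0 + 1] +
        (1 - fi) * fj * ev[i0 + 1, j1 + 1] +
        fi * (1 - fj) * ev[i1 + 1, j0 + 1] + fi * fj * ev[i1 + 1, j1 + 1]
      g2 <- ((de - ref[i, j]) / tol)^2 + (dx^2 + dy^2) / dta^2
      if (g2 < best) best <- g2
    }
    out[i, j] <- sqrt(best)
  }
  out
}

# AUC as the concordant-pair (tie = 1/2) probability
oracle_auc_pairs <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# step-by-step Ward agglomeration (Lance-Williams, ward.D2 form)
oracle_ward_heights <- function(D) {
  n <- nrow(D)
  active <- seq_len(n)
  size <- rep(1, n)
  d <- D^2                       # work on squared distances
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bestv) { bestv <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    ni <- size[i]; nj <- size[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- size[k]
      d[i, k] <- d[k, i] <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] -
                               nk * d[i, j]) / (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# scalar-loop modulation complexity score
oracle_mcs <- function(arc, machine = arc$machine) {
  n <- length(arc$cum_weight); np <- ncol(arc$bankA)
  wclip <- function(k, p) {
    b <- machine$boundaries
    max(0, min(b[p + 1], arc$jaws[k, "y2"]) - max(b[p], arc$jaws[k, "y1"]))
  }
  gmax <- numeric(np); wmax <- numeric(np)
  for (p in seq_len(np)) for (k in seq_len(n)) {
    if (oracle_open(arc, k, p, machine)) {
      gmax[p] <- max(gmax[p], arc$bankB[k, p] - arc$bankA[k, p])
      wmax[p] <- max(wmax[p], wclip(k, p))
    }
  }
  denom <- sum(gmax * wmax)
  aav <- numeric(n); lsv <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (p in seq_len(np)) if (oracle_open(arc, k, p, machine))
      s <- s + (arc$bankB[k, p] - arc$bankA[k, p]) * wclip(k, p)
    aav[k] <- if (denom > 0) s / denom else 1
    l <- 1
    for (bank in 1:2) {
      pos <- if (bank == 1) arc$bankA else arc$bankB
      idx <- which(vapply(seq_len(np), function(p)
        oracle_open(arc, k, p, machine), TRUE))
      if (length(idx) < 2) next
      x <- pos[k, idx]
      pm <- max(x) - min(x)
      if (pm <= 0) next
      tot <- 0
      for (i in seq_len(length(idx) - 1))
        tot <- tot + (pm - abs(x[i] - x[i + 1]))
      l <- l * tot / ((length(idx) - 1) * pm)
    }
    lsv[k] <- l
  }
  out <- 0
  for (k in seq_len(n - 1)) {
    dmu <- arc$cum_weight[k + 1] - arc$cum_weight[k]
    out <- out + dmu * (aav[k] * lsv[k] + aav[k + 1] * lsv[k + 1]) / 2
  }
  out
}

# beam modulation via 0.05 mm per-pair rasterized interval unions
oracle_bm <- function(arc, machine = arc$machine, step = 0.05) {
  n <- length(arc$cum_weight); np <- ncol(arc$bankA)
  b <- machine$boundaries
  a_union <- 0
  area_cp <- numeric(n)
  for (p in seq_len(np)) {
    xs <- seq(-machine$field_extent, machine$field_extent, by = step) + step / 2
    covered <- rep(FALSE, length(xs))
    wmax <- 0
    for (k in seq_len(n)) {
      if (!oracle_open(arc, k, p, machine)) next
      covered <- covered | (xs > arc$bankA[k, p] & xs < arc$bankB[k, p])
      wmax <- max(wmax, min(b[p + 1], arc$jaws[k, "y2"]) -
                    max(b[p], arc$jaws[k, "y1"]))
    }
    a_union <- a_union + sum(covered) * step * wmax
  }
  for (k in seq_len(n)) for (p in seq_len(np)) {
    if (!oracle_open(arc, k, p, machine)) next
    w <- min(b[p + 1], arc$jaws[k, "y2"]) - max(b[p], arc$jaws[k, "y1"])
    area_cp[k] <- area_cp[k] + (arc$bankB[k, p] - arc$bankA[k, p]) * w
  }
  wsum <- 0
  for (k in seq_len(n - 1))
    wsum <- wsum + (arc$cum_weight[k + 1] - arc$cum_weight[k]) *
      (area_cp[k] + area_cp[k + 1]) / 2
  1 - wsum / a_union
}
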