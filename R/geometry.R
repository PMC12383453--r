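#' Aperture geometry of a single control point
#'
#' The beam aperture at a control point is the union over open leaf pairs of
#' the rectangles `[bankA_i, bankB_i] x [pair y-extent clipped to Y jaws]`.
#' A pair is open when its gap exceeds the machine `min_gap` and it overlaps
#' the Y-jaw aperture; closed pairs are excluded from all statistics.
#'
#' @param cp a control point: a list with numeric `bankA`, `bankB`
#'   (length `n_pairs`, mm) and `jaws` (x1, x2, y1, y2, mm), e.g. from
#'   [control_point()].
#' @param machine a [machine_spec()].
#' @return an object of class `aperture_shape`: list with `area` (mm^2),
#'   `perimeter` (mm), `side_length` (exposed leaf-side edge length, mm),
#'   `open_gaps` (mm, one per open pair), `open` (logical per pair).
#' @export
aperture_geometry <- function(cp, machine = machine_spec()) {
  arc <- list(bankA = matrix(cp$bankA, 1), bankB = matrix(cp$bankB, 1),
              jaws = matrix(as.numeric(cp$jaws), 1, 4,
                            dimnames = list(NULL, c("x1", "x2", "y1", "y2"))),
              machine = machine)
  g <- arc_aperture_stats(arc, machine)
  out <- list(area = g$area[1], perimeter = g$perimeter[1],
              side_length = g$side_length[1],
              open_gaps = (arc$bankB - arc$bankA)[1, g$open[1, ]],
              open = g$open[1, ])
  class(out) <- "aperture_shape"
  out
}

#' Extract one control point from an arc
#'
#' @param arc an [arc_beam()].
#' @param i control-point index.
#' @return a list with `index`, `cum_weight`, `gantry_angle`, `bankA`,
#'   `bankB`, `jaws`.
#' @export
control_point <- function(arc, i) {
  list(index = i, cum_weight = arc$cum_weight[i],
       gantry_angle = arc$gantry_angle[i],
       bankA = arc$bankA[i, ], bankB = arc$bankB[i, ],
       jaws = arc$jaws[i, ])
}

# Vectorized per-CP aperture statistics for a whole arc.
# Returns per-CP vectors: area, perimeter, side_length, tgi_num (sum over
# internal both-open boundaries of |dxA| + |dxB|), gap_sum (sum of open
# gaps), plus the open mask and clipped widths matrix.
arc_aperture_stats <- function(arc, machine = arc$machine) {
  n_cp <- nrow(arc$bankA)
  np <- machine$n_pairs
  b <- machine$boundaries
  lo <- matrix(b[-length(b)], n_cp, np, byrow = TRUE)
  hi <- matrix(b[-1],         n_cp, np, byrow = TRUE)
  # pair widths clipped to the Y-jaw aperture
  w <- pmin(hi, arc$jaws[, "y2"]) - pmax(lo, arc$jaws[, "y1"])
  w[w < 0] <- 0  # pmax(0, .) would drop the dim attributes
  gap <- arc$bankB - arc$bankA
  open <- gap > machine$min_gap & w > 0
  gap_o <- gap * open
  area <- rowSums(gap_o * w)
  # horizontal exposure at the n_pairs + 1 boundaries between rows of pairs:
  # pad with a closed phantom pair at each end
  z <- matrix(0, n_cp, 1)
  Ao <- arc$bankA * open; Bo <- arc$bankB * open
  A1 <- cbind(z, Ao); A2 <- cbind(Ao, z)
  B1 <- cbind(z, Bo); B2 <- cbind(Bo, z)
  o1 <- cbind(matrix(FALSE, n_cp, 1), open)
  o2 <- cbind(open, matrix(FALSE, n_cp, 1))
  len1 <- B1 - A1; len2 <- B2 - A2
  overlap <- pmin(B1, B2) - pmax(A1, A2)
  overlap[overlap < 0 | !(o1 & o2)] <- 0
  # symmetric-difference measure where both open; full gap where one open
  expo <- (len1 + len2 - 2 * overlap) * (o1 & o2) +
    len1 * (o1 & !o2) + len2 * (o2 & !o1)
  side_length <- rowSums(expo)
  perimeter <- side_length + rowSums(2 * w * open)
  # tongue-and-groove numerator: internal both-open boundaries only
  both <- open[, -np, drop = FALSE] & open[, -1, drop = FALSE]
  dA <- abs(arc$bankA[, -1, drop = FALSE] - arc$bankA[, -np, drop = FALSE])
  dB <- abs(arc$bankB[, -1, drop = FALSE] - arc$bankB[, -np, drop = FALSE])
  tgi_num <- rowSums((dA + dB) * both)
  list(area = area, perimeter = perimeter, side_length = side_length,
       tgi_num = tgi_num, gap_sum = rowSums(gap_o),
       open = open, width = w, gap = gap)
}

# total length of the union of intervals [a_i, b_i]
interval_union_length <- function(a, b) {
  if (!length(a)) return(0)
  o <- order(a)
  a <- a[o]; b <- b[o]
  prev_end <- c(-Inf, cummax(b)[-length(b)])
  sum(pmax(0, b - pmax(a, prev_end)))
}

# column/row maxima without per-element apply() overhead
col_max <- function(M) {
  out <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) out[j] <- max(M[, j])
  out
}
row_max <- function(M) {
  out <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) {
    mj <- M[, j]
    sel <- mj > out
    out[sel] <- mj[sel]
  }
  out
}
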