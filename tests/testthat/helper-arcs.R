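# Builders for small hand-laid arcs used across the metric tests.

toy_machine <- function(n_pairs = 6, width = 5, ...) {
  machine_spec(leaf_widths = rep(width, n_pairs), ...)
}

# arc from explicit per-CP leaf matrices; defaults give a wide-open jaw
toy_arc <- function(bankA, bankB, cum_weight = NULL, gantry = NULL,
                    jaws = NULL, total_mu = 100, dose_per_fraction = 10,
                    machine = toy_machine(n_pairs = ncol(as.matrix(bankA)))) {
  bankA <- as.matrix(bankA); bankB <- as.matrix(bankB)
  n_cp <- nrow(bankA)
  if (is.null(cum_weight)) cum_weight <- seq(0, 1, length.out = n_cp)
  if (is.null(gantry)) gantry <- seq(180, 180 + 2 * (n_cp - 1), length.out = n_cp)
  if (is.null(jaws)) {
    ext <- machine$field_extent
    half_y <- sum(machine$leaf_widths) / 2
    jaws <- c(-ext, ext, -half_y, half_y)
  }
  arc_beam(arc_id = "T1", patient_id = "PT", treatment_date = as.Date("2022-06-01"),
           cum_weight = cum_weight, gantry_angle = gantry,
           bankA = bankA, bankB = bankB, jaws = jaws,
           total_mu = total_mu, dose_per_fraction = dose_per_fraction,
           machine = machine)
}

# static rectangular aperture: pairs `open_idx` at [-half_gap, half_gap]
rect_arc <- function(n_cp = 5, n_pairs = 6, open_idx = 2:5, gap = 20,
                     machine = toy_machine(n_pairs = n_pairs), ...) {
  bankA <- matrix(0, n_cp, n_pairs); bankB <- matrix(0, n_cp, n_pairs)
  bankA[, open_idx] <- -gap / 2
  bankB[, open_idx] <- gap / 2
  toy_arc(bankA, bankB, machine = machine, ...)
}

# random small arc for oracle sweeps: <= 10 CPs, <= 8 pairs, smooth-ish
random_small_arc <- function(n_cp = sample(3:10, 1),
                             n_pairs = sample(4:8, 1)) {
  # >= 3 open pairs: with exactly 2, LSV (hence MCS) is identically zero
  # and the MCS in (0, 1] bound does not apply
  machine <- toy_machine(n_pairs = n_pairs, width = sample(c(2.5, 5), 1))
  open_idx <- sort(sample(n_pairs, sample(3:n_pairs, 1)))
  center <- matrix(rnorm(n_cp * length(open_idx), 0, 10), n_cp)
  gap <- matrix(runif(n_cp * length(open_idx), 1, 40), n_cp)
  bankA <- matrix(0, n_cp, n_pairs); bankB <- matrix(0, n_cp, n_pairs)
  bankA[, open_idx] <- center - gap / 2
  bankB[, open_idx] <- center + gap / 2
  cw <- c(0, sort(runif(n_cp - 2)), 1)
  toy_arc(bankA, bankB, cum_weight = cw,
          gantry = seq(0, sample(30:120, 1), length.out = n_cp) + 100,
          total_mu = runif(1, 50, 500), machine = machine)
}
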