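#' Linac / MLC machine specification
#'
#' Describes the multileaf collimator layout and the mechanical limits of the
#' treatment machine that constrain arc delivery. The default corresponds to a
#' high-definition 120-leaf MLC (60 pairs: 14 outer 5 mm pairs, 32 inner
#' 2.5 mm pairs, 14 outer 5 mm pairs, total 220 mm) on an SRS-capable linac.
#'
#' @param leaf_widths numeric vector of per-pair leaf widths in mm (projected
#'   at isocenter), one entry per leaf pair.
#' @param max_dose_rate maximum dose rate, MU/min.
#' @param max_gantry_speed maximum gantry speed, deg/s.
#' @param max_leaf_speed maximum leaf speed, cm/s.
#' @param min_gap minimum dosimetric leaf gap below which a pair is considered
#'   closed, mm.
#' @param field_extent half-extent of allowed leaf positions, mm: leaf tips
#'   must stay within `[-field_extent, field_extent]`.
#' @return an object of class `machine_spec`.
#' @examples
#' m <- machine_spec()
#' sum(m$leaf_widths)  # 220 mm for the HD120 layout
#' @export
machine_spec <- function(leaf_widths = hd120_leaf_widths(),
                         max_dose_rate = 1400,
                         max_gantry_speed = 4.8,
                         max_leaf_speed = 2.5,
                         min_gap = 0.5,
                         field_extent = 160) {
  stopifnot(is.numeric(leaf_widths), length(leaf_widths) >= 1,
            all(leaf_widths > 0))
  limits <- c(max_dose_rate, max_gantry_speed, max_leaf_speed, field_extent)
  if (any(!is.finite(limits)) || any(limits <= 0))
    stop("all machine limits must be positive and finite")
  if (min_gap < 0) stop("min_gap must be >= 0")
  m <- list(leaf_widths = as.numeric(leaf_widths),
            n_pairs = length(leaf_widths),
            max_dose_rate = max_dose_rate,
            max_gantry_speed = max_gantry_speed,
            max_leaf_speed = max_leaf_speed,
            min_gap = min_gap,
            field_extent = field_extent,
            # leaf-pair boundaries across the field, centred on the midline
            boundaries = leaf_boundaries(as.numeric(leaf_widths)))
  class(m) <- "machine_spec"
  m
}

#' @rdname machine_spec
#' @export
hd120_leaf_widths <- function() {
  c(rep(5, 14), rep(2.5, 32), rep(5, 14))
}

leaf_boundaries <- function(widths) {
  b <- c(0, cumsum(widths))
  b - sum(widths) / 2
}

#' @export
print.machine_spec <- function(x, ...) {
  cat("<machine_spec> ", x$n_pairs, " leaf pairs, total width ",
      sum(x$leaf_widths), " mm\n", sep = "")
  cat("  limits: ", x$max_dose_rate, " MU/min, ", x$max_gantry_speed,
      " deg/s gantry, ", x$max_leaf_speed, " cm/s leaf; min gap ",
      x$min_gap, " mm\n", sep = "")
  invisible(x)
}

#' Read or write a machine specification as JSON
#'
#' @param machine a `machine_spec`.
#' @param path file path.
#' @return `read_machine_spec` returns a `machine_spec`;
#'   `write_machine_spec` returns `path` invisibly.
#' @export
write_machine_spec <- function(machine, path) {
  stopifnot(inherits(machine, "machine_spec"))
  keep <- c("leaf_widths", "max_dose_rate", "max_gantry_speed",
            "max_leaf_speed", "min_gap", "field_extent")
  jsonlite::write_json(machine[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_machine_spec
#' @export
read_machine_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  machine_spec(leaf_widths = x$leaf_widths,
               max_dose_rate = x$max_dose_rate,
               max_gantry_speed = x$max_gantry_speed,
               max_leaf_speed = x$max_leaf_speed,
               min_gap = x$min_gap,
               field_extent = x$field_extent)
}
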