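#' Gamma-analysis criteria
#'
#' @param dose_diff dose-difference criterion, percent of the normalization
#'   dose (default 3).
#' @param dta distance-to-agreement criterion, mm (default 1).
#' @param low_dose_threshold percent of the normalization dose below which
#'   reference points are excluded from the passing rate (default 10).
#' @param normalization `"global"` (percentages of the reference maximum) or
#'   `"local"` (percentages of the local reference dose).
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff = 3, dta = 1, low_dose_threshold = 10,
                           normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  if (dose_diff <= 0 || dta <= 0 || low_dose_threshold <= 0)
    stop("all gamma criteria must be positive")
  structure(list(dose_diff = dose_diff, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' 2D dose image
#'
#' @param values numeric matrix of non-negative dose values (arbitrary dose
#'   units, consistent between compared images).
#' @param pixel_spacing pixel spacing, mm (default 1; the EPID panel the
#'   synthetic engine stands in for has 0.336 mm pixels, see the vignette).
#' @return an object of class `dose_image`.
#' @export
dose_image <- function(values, pixel_spacing = 1.0) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("dose values must be non-negative")
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  structure(list(values = values, pixel_spacing = pixel_spacing),
            class = "dose_image")
}

#' Gamma-index map between two dose images
#'
#' For every reference pixel, the minimum over a search disk (radius
#' `search_radius_factor * dta`, evaluated image sampled at `1/upsample`
#' pixel steps by bilinear interpolation) of
#' \eqn{\sqrt{(\Delta D/\Delta D_{tol})^2 + (\Delta r/\mathrm{DTA})^2}}.
#' Under global normalization \eqn{\Delta D_{tol}} is `dose_diff`% of the
#' reference maximum; under local normalization, of the local reference dose.
#'
#' @param reference,evaluated [dose_image()]s on the same grid.
#' @param criteria a [gamma_criteria()].
#' @param search_radius_factor search radius in units of `dta`.
#' @param upsample sub-pixel sampling factor of the evaluated image.
#' @return numeric matrix of gamma values (same shape as the images).
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      search_radius_factor = 3, upsample = 10) {
  stopifnot(inherits(reference, "dose_image"), inherits(evaluated, "dose_image"))
  if (!identical(dim(reference$values), dim(evaluated$values)) ||
      reference$pixel_spacing != evaluated$pixel_spacing)
    stop("reference and evaluated images must share grid and spacing")
  dmax <- max(reference$values)
  if (dmax <= 0) stop("reference image has no positive dose")
  tol_global <- criteria$dose_diff / 100 * dmax
  local_frac <- if (criteria$normalization == "local")
    criteria$dose_diff / 100 else 0
  .gamma_map_cpp(reference$values, evaluated$values,
                 reference$pixel_spacing, criteria$dta,
                 tol_global, local_frac,
                 search_radius_factor * criteria$dta, as.integer(upsample))
}

#' Gamma passing rate
#'
#' Percentage of reference pixels at or above the low-dose threshold whose
#' gamma value is `<= 1`.
#'
#' @param gamma numeric matrix from [gamma_map()].
#' @param reference the reference [dose_image()] (for the dose threshold).
#' @param criteria a [gamma_criteria()].
#' @return GPR in percent.
#' @export
passing_rate <- function(gamma, reference, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_image"))
  if (!identical(dim(gamma), dim(reference$values)))
    stop("gamma map and reference image shapes differ")
  if (max(reference$values) <= 0)
    stop("reference image has no positive dose")
  thr <- criteria$low_dose_threshold / 100 * max(reference$values)
  mask <- reference$values >= thr
  if (!any(mask)) stop("no reference pixels above the low-dose threshold")
  100 * sum(gamma[mask] <= 1) / sum(mask)
}
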