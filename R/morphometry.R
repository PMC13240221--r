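# Stereological morphometry of a sectioned ROI. Notation: N_f fibers, N_t
# trimmed fibers, N_c = N_f - N_t/2 corrected count, A_f total fiber area,
# P_f total fiber perimeter, A_ROI / P_ROI the ROI area and perimeter, A_e
# total endomysium area, Abar mean fiber area, tbar mean endomysium
# thickness.

#' Corrected fiber count
#'
#' Fibers cut by the ROI boundary are counted as half fibers:
#' N_c = N_f - N_t / 2. The result may be half-integral and is never
#' rounded.
#'
#' @param n_total total number of fibers in the ROI.
#' @param n_trimmed number of fibers cut by the ROI boundary.
#' @return corrected (possibly half-integral) fiber count.
#' @export
corrected_fiber_count <- function(n_total, n_trimmed) {
  stopifnot(n_total >= 0, n_trimmed >= 0)
  if (n_trimmed > n_total)
    stop("n_trimmed exceeds n_total")
  n_total - n_trimmed / 2
}

#' Mean fiber cross-sectional area
#'
#' Total fiber area (including the partial area of trimmed fibers) divided
#' by the corrected fiber count.
#'
#' @param total_fiber_area_um2 summed fiber area A_f (um^2).
#' @param n_corrected corrected fiber count N_c (> 0).
#' @return mean fiber area (um^2).
#' @export
mean_fiber_area <- function(total_fiber_area_um2, n_corrected) {
  stopifnot(total_fiber_area_um2 >= 0)
  if (n_corrected <= 0) stop("corrected fiber count must be positive")
  total_fiber_area_um2 / n_corrected
}

#' Total endomysium area
#'
#' The endomysial space is everything in the ROI that is not muscle fiber:
#' A_e = A_ROI - A_f.
#'
#' @param roi_area_um2 ROI area (um^2).
#' @param total_fiber_area_um2 total fiber area (um^2), at most the ROI area.
#' @return endomysium area (um^2).
#' @export
total_endomysium_area <- function(roi_area_um2, total_fiber_area_um2) {
  stopifnot(roi_area_um2 >= 0, total_fiber_area_um2 >= 0)
  if (total_fiber_area_um2 > roi_area_um2 * (1 + 1e-12))
    stop("total fiber area exceeds ROI area (segmentation inconsistency)")
  max(roi_area_um2 - total_fiber_area_um2, 0)
}

#' Mean endomysium thickness
#'
#' The endomysium forms a band between fibers whose total mid-line length is
#' approximated by half the total fiber perimeter corrected for the ROI
#' boundary: tbar = A_e / (P_f / 2 - P_ROI). For small ROIs with few fibers
#' the denominator can be non-positive; the result is then flagged undefined
#' (`NA` with a warning), never a silent negative thickness. A section with
#' no endomysium at all has thickness 0 regardless.
#'
#' @param endo_area_um2 total endomysium area A_e (um^2).
#' @param total_fiber_perimeter_um total fiber perimeter P_f (um).
#' @param roi_perimeter_um ROI perimeter P_ROI (um).
#' @return thickness in um, or `NA` when undefined.
#' @export
mean_endomysium_thickness <- function(endo_area_um2, total_fiber_perimeter_um,
                                      roi_perimeter_um) {
  stopifnot(endo_area_um2 >= 0, total_fiber_perimeter_um >= 0,
            roi_perimeter_um >= 0)
  if (endo_area_um2 == 0) return(0)
  denom <- total_fiber_perimeter_um / 2 - roi_perimeter_um
  if (denom <= 0) {
    warning("thickness undefined: P_f/2 does not exceed P_ROI ",
            "(too few or too large fibers in the ROI)")
    return(NA_real_)
  }
  endo_area_um2 / denom
}

#' Square-approximation estimate of the total fiber perimeter
#'
#' When only pixel counts are available (fill-stain analysis), fibers are
#' treated as squares of the mean fiber area, so
#' P_f ~ 4 * sqrt(Abar) * N_c.
#'
#' @param mean_fiber_area_um2 mean fiber area (um^2).
#' @param n_corrected corrected fiber count.
#' @return estimated total fiber perimeter (um).
#' @export
square_perimeter_estimate <- function(mean_fiber_area_um2, n_corrected) {
  stopifnot(mean_fiber_area_um2 >= 0, n_corrected >= 0)
  4 * sqrt(mean_fiber_area_um2) * n_corrected
}

#' Assemble the section-level morphometry
#'
#' Computes the four headline parameters (mean fiber area, mean endomysium
#' thickness, endomysium-to-fiber area ratio, endomysium area per fiber) and
#' all primitives from either staining variant:
#' \describe{
#'   \item{boundary_stain}{per-fiber records carry measured areas and
#'     perimeters; P_f is the sum of fiber perimeters (trimmed fibers
#'     contribute their clipped perimeter including the cut edge -- the
#'     P_ROI subtraction in the thickness formula corrects for the ROI
#'     boundary).}
#'   \item{fill_square_approx}{pixel counts plus manually counted total and
#'     trimmed fibers; P_f is estimated by [square_perimeter_estimate()].}
#' }
#'
#' @param roi a [roi_geometry()].
#' @param fibers data frame with columns `area_um2`, `perimeter_um`,
#'   `trimmed` (boundary variant).
#' @param counts a `binary_counts` object (fill variant).
#' @param n_total,n_trimmed manual fiber counts (fill variant).
#' @param variant `"boundary_stain"` or `"fill_square_approx"`.
#' @return object of class `section_morphometry` with fields `variant`,
#'   `n_fibers_total`, `n_trimmed`, `n_corrected`, `roi_area_um2`,
#'   `roi_perimeter_um`, `total_fiber_area_um2`, `total_fiber_perimeter_um`,
#'   `total_endomysium_area_um2`, `mean_fiber_area_um2`,
#'   `mean_endomysium_thickness_um`, `thickness_defined`,
#'   `endo_to_fiber_area_ratio`, `endo_area_per_fiber_um2`.
#' @export
section_morphometry <- function(roi, fibers = NULL, counts = NULL,
                                n_total = NULL, n_trimmed = NULL,
                                variant = c("boundary_stain",
                                            "fill_square_approx")) {
  variant <- match.arg(variant)
  stopifnot(inherits(roi, "roi_geometry"))
  if (variant == "boundary_stain") {
    if (is.null(fibers)) stop("boundary variant requires per-fiber records")
    n_f <- nrow(fibers)
    n_t <- sum(fibers$trimmed)
    a_f <- sum(fibers$area_um2)
    p_f <- sum(fibers$perimeter_um)
  } else {
    if (is.null(counts) || is.null(n_total) || is.null(n_trimmed))
      stop("fill variant requires binary counts and manual fiber counts")
    stopifnot(inherits(counts, "binary_counts"))
    n_f <- n_total; n_t <- n_trimmed
    a_f <- counts$n_fiber_pixels * counts$pixel_size_um^2
    p_f <- NA_real_  # estimated below from the mean area
  }
  n_c <- corrected_fiber_count(n_f, n_t)
  a_e <- total_endomysium_area(roi$area_um2, a_f)
  abar <- if (n_c > 0) mean_fiber_area(a_f, n_c) else NA_real_
  if (variant == "fill_square_approx")
    p_f <- square_perimeter_estimate(if (is.na(abar)) 0 else abar, n_c)
  tbar <- withCallingHandlers(
    mean_endomysium_thickness(a_e, p_f, roi$perimeter_um),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(
    variant = variant,
    n_fibers_total = n_f, n_trimmed = n_t, n_corrected = n_c,
    roi_area_um2 = roi$area_um2, roi_perimeter_um = roi$perimeter_um,
    total_fiber_area_um2 = a_f, total_fiber_perimeter_um = p_f,
    total_endomysium_area_um2 = a_e,
    mean_fiber_area_um2 = abar,
    mean_endomysium_thickness_um = tbar,
    thickness_defined = !is.na(tbar),
    endo_to_fiber_area_ratio = if (a_f > 0) a_e / a_f else
      (if (a_e == 0) 0 else NA_real_),
    endo_area_per_fiber_um2 = if (n_c > 0) a_e / n_c else NA_real_
  ), class = "section_morphometry")
}

#' @export
print.section_morphometry <- function(x, ...) {
  cat(sprintf("section_morphometry [%s]\n", x$variant))
  cat(sprintf("  N_f %d (N_t %d, N_c %.1f);  A_f %.0f um^2;  A_e %.0f um^2\n",
              x$n_fibers_total, x$n_trimmed, x$n_corrected,
              x$total_fiber_area_um2, x$total_endomysium_area_um2))
  cat(sprintf("  mean fiber area %.1f um^2;  thickness %s um;  A_e/A_f %.4f;  A_e/N_c %.1f\n",
              x$mean_fiber_area_um2,
              if (x$thickness_defined)
                sprintf("%.2f", x$mean_endomysium_thickness_um) else "undefined",
              x$endo_to_fiber_area_ratio, x$endo_area_per_fiber_um2))
  invisible(x)
}

#' @export
as.data.frame.section_morphometry <- function(x, ...) {
  data.frame(variant = x$variant, n_fibers_total = x$n_fibers_total,
             n_trimmed = x$n_trimmed, n_corrected = x$n_corrected,
             roi_area_um2 = x$roi_area_um2,
             roi_perimeter_um = x$roi_perimeter_um,
             total_fiber_area_um2 = x$total_fiber_area_um2,
             total_fiber_perimeter_um = x$total_fiber_perimeter_um,
             total_endomysium_area_um2 = x$total_endomysium_area_um2,
             mean_fiber_area_um2 = x$mean_fiber_area_um2,
             mean_endomysium_thickness_um = x$mean_endomysium_thickness_um,
             thickness_defined = x$thickness_defined,
             endo_to_fiber_area_ratio = x$endo_to_fiber_area_ratio,
             endo_area_per_fiber_um2 = x$endo_area_per_fiber_um2)
}
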