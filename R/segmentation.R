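# Segmentation of the two staining modalities. The boundary modality (bright
# basement-membrane network, as in laminin/collagen-IV staining) is
# thresholded and the complement decomposed into fibers; the fill modality
# (bright endomysial band, as in collagen I/III staining) is reduced to pixel
# counts. Images are numeric matrices in [0, 1], rows = y, columns = x.

check_image_roi <- function(image, roi) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (nrow(image) != roi$ny || ncol(image) != roi$nx)
    stop(sprintf("image size %d x %d does not match ROI %d x %d at %g um/px",
                 nrow(image), ncol(image), roi$ny, roi$nx, roi$pixel_size_um))
}

auto_threshold <- function(image, threshold) {
  if (identical(threshold, "auto")) EBImage::otsu(image, range = range(image))
  else as.numeric(threshold)
}

border_labels <- function(lab) {
  u <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  u[u > 0L]
}

#' Segment muscle fibers from a boundary-stained image
#'
#' Thresholds the bright basement-membrane network (automatic inter-class
#' variance threshold by default), optionally closes small gaps in the
#' network, and decomposes the complement into 4-connected components.
#' Components below `min_fiber_area_um2` are discarded. A border-touching
#' component much larger than its peers (more than 25 times the median
#' component area, or most of the ROI) is treated as background rather than
#' a fiber, which handles empty images and mosaics with unstained outer
#' margin. Remaining components are fibers; per-fiber area (pixel count times
#' pixel area), perimeter and Feret diameters (both from the convex hull of
#' the pixel centres -- fiber cross-sections are convex to good
#' approximation) and a trimmed flag (any pixel on the image border) are
#' computed.
#'
#' @param image numeric matrix in [0, 1].
#' @param roi a [roi_geometry()] consistent with the image.
#' @param threshold `"auto"` or a fixed numeric threshold.
#' @param min_fiber_area_um2 minimum fiber area kept (um^2).
#' @param closing_radius_um radius of the morphological closing applied to
#'   the boundary network (0 disables it; use ~1 um for noisy stains).
#' @return object of class `fiber_segmentation`: list with `fibers` (data
#'   frame: label, area_um2, perimeter_um, feret_min_um, feret_max_um,
#'   centroid_x_um, centroid_y_um, trimmed), `label_image`, `threshold`.
#' @export
segment_boundary_stain <- function(image, roi, threshold = "auto",
                                   min_fiber_area_um2 = 10,
                                   closing_radius_um = 0) {
  check_image_roi(image, roi)
  px <- roi$pixel_size_um
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), feret_min_um = numeric(0),
                      feret_max_um = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), trimmed = logical(0))
  thr <- if (identical(threshold, "auto") && diff(range(image)) < 1e-9) {
    Inf  # flat image: no boundary network at all
  } else auto_threshold(image, threshold)
  mask <- image > thr
  if (closing_radius_um > 0) {
    r <- max(1L, round(closing_radius_um / px))
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  lab <- EBImage::bwlabel((!mask) * 1L)
  nlab <- max(lab)
  if (nlab == 0) {
    return(structure(list(fibers = empty,
                          label_image = matrix(0L, roi$ny, roi$nx),
                          threshold = thr), class = "fiber_segmentation"))
  }
  sizes <- tabulate(lab, nbins = nlab)
  keep <- which(sizes * px^2 >= min_fiber_area_um2)
  on_border <- border_labels(lab)
  # background rule: border-touching giants are not fibers
  if (length(keep) > 0) {
    areas <- sizes[keep]
    bg <- vapply(seq_along(keep), function(k) {
      if (!(keep[k] %in% on_border)) return(FALSE)
      others <- areas[-k]
      if (length(others) == 0) return(areas[k] * px^2 > 0.5 * roi$area_um2)
      areas[k] > 25 * stats::median(others) ||
        areas[k] * px^2 > 0.5 * roi$area_um2
    }, logical(1))
    keep <- keep[!bg]
  }
  if (length(keep) == 0) {
    return(structure(list(fibers = empty,
                          label_image = matrix(0L, roi$ny, roi$nx),
                          threshold = thr), class = "fiber_segmentation"))
  }
  remap <- integer(nlab); remap[keep] <- seq_along(keep)
  out_lab <- matrix(0L, roi$ny, roi$nx)
  pos <- lab > 0L
  out_lab[pos] <- remap[lab[pos]]
  pix <- split(which(out_lab > 0L), out_lab[out_lab > 0L])
  ny <- roi$ny
  rec <- lapply(seq_along(pix), function(k) {
    idx <- pix[[k]]
    r <- (idx - 1L) %% ny + 1L
    cc <- (idx - 1L) %/% ny + 1L
    xs <- (cc - 0.5) * px; ys <- (r - 0.5) * px
    pts <- cbind(xs, ys)
    hull <- pts[rev(grDevices::chull(pts)), , drop = FALSE]  # CCW order
    # the region extends half a pixel beyond the sampled centres; expand the
    # hull accordingly so that perimeter and Feret widths are unbiased
    if (nrow(hull) >= 3) hull <- offset_convex(hull, -px / 2)
    fer <- feret_diameters(hull)
    data.frame(label = k,
               area_um2 = length(idx) * px^2,
               perimeter_um = poly_perimeter(hull),
               feret_min_um = fer[["feret_min"]],
               feret_max_um = fer[["feret_max"]],
               centroid_x_um = mean(xs), centroid_y_um = mean(ys),
               trimmed = any(r == 1L | r == ny | cc == 1L | cc == roi$nx))
  })
  structure(list(fibers = do.call(rbind, rec), label_image = out_lab,
                 threshold = thr),
            class = "fiber_segmentation")
}

#' Binarize a fill-stained image into endomysium and fiber pixel counts
#'
#' Pixels above the threshold are endomysium (the stained connective
#' tissue), the rest are muscle fiber; the two counts always partition the
#' ROI. Areas follow as count times squared pixel size.
#'
#' @inheritParams segment_boundary_stain
#' @return object of class `binary_counts`: `n_roi_pixels`,
#'   `n_endomysium_pixels`, `n_fiber_pixels`, `pixel_size_um`, `threshold`.
#' @export
binarize_fill_stain <- function(image, roi, threshold = "auto") {
  check_image_roi(image, roi)
  thr <- if (identical(threshold, "auto") && diff(range(image)) < 1e-9) {
    Inf  # flat image: nothing stained
  } else auto_threshold(image, threshold)
  n_endo <- sum(image > thr)
  structure(list(n_roi_pixels = length(image),
                 n_endomysium_pixels = n_endo,
                 n_fiber_pixels = length(image) - n_endo,
                 pixel_size_um = roi$pixel_size_um,
                 threshold = thr),
            class = "binary_counts")
}

#' Count total and trimmed fibers from a label image
#'
#' Automates the manual count: every label is a fiber; a fiber with at least
#' one pixel on the image border counts as trimmed.
#'
#' @param label_image integer matrix of fiber labels (0 = background).
#' @return list(n_total, n_trimmed).
#' @export
count_fibers_manual_emulation <- function(label_image) {
  labs <- sort(unique(label_image[label_image > 0L]))
  list(n_total = length(labs),
       n_trimmed = sum(labs %in% border_labels(label_image)))
}

#' Fiber-type fractions from per-stain positivity calls
#'
#' Slow (type I) and fast (type II) myosin isoforms are assessed on
#' separately stained serial sections, so the two fractions are independent
#' and need not sum to 1 (hybrid fibers are positive for both).
#'
#' @param n_fibers total number of fibers assessed.
#' @param mhcs_positive logical vector or count of slow-MHC-positive fibers.
#' @param mhcf_positive logical vector or count of fast-MHC-positive fibers.
#' @return list(fraction_type_I, fraction_type_II); a fraction is `NA` when
#'   its stain was not assessed (`NULL` input).
#' @export
fiber_type_fractions <- function(n_fibers, mhcs_positive = NULL,
                                 mhcf_positive = NULL) {
  if (n_fibers < 1) stop("fiber_type_fractions: no fibers")
  as_count <- function(x) {
    if (is.null(x)) return(NA_real_)
    n <- if (is.logical(x)) sum(x) else as.numeric(x)
    if (n < 0 || n > n_fibers) stop("positivity count outside [0, n_fibers]")
    n / n_fibers
  }
  f1 <- as_count(mhcs_positive); f2 <- as_count(mhcf_positive)
  if (is.na(f1) && is.na(f2))
    warning("no positivity data; both fractions undefined")
  list(fraction_type_I = f1, fraction_type_II = f2)
}
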