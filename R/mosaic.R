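# Synthetic muscle-mosaic generator: perturbed-lattice Voronoi tessellation,
# per-cell inward offset to create the endomysial band, and rendering of the
# two staining modalities (basement-membrane boundary lines; connective-tissue
# fill). Every quantity downstream estimators target is returned as ground
# truth.

#' Physical ROI geometry
#'
#' A rectangular region of interest with its pixel size. Houses the ROI area
#' and perimeter used by the stereological formulas.
#'
#' @param width_um,height_um ROI dimensions in micrometres.
#' @param pixel_size_um physical size of one pixel in micrometres.
#' @return object of class `roi_geometry` with fields `width_um`, `height_um`,
#'   `pixel_size_um`, `area_um2`, `perimeter_um`, `nx`, `ny` (image size in
#'   pixels, columns x rows).
#' @export
roi_geometry <- function(width_um, height_um, pixel_size_um) {
  stopifnot(width_um > 0, height_um > 0, pixel_size_um > 0)
  structure(list(
    width_um = width_um, height_um = height_um,
    pixel_size_um = pixel_size_um,
    area_um2 = width_um * height_um,
    perimeter_um = 2 * (width_um + height_um),
    nx = as.integer(round(width_um / pixel_size_um)),
    ny = as.integer(round(height_um / pixel_size_um))
  ), class = "roi_geometry")
}

#' Configuration for the synthetic fiber mosaic
#'
#' Defaults emulate a soleus-muscle ROI of roughly 100 fibers: mean fiber
#' cross-sectional area ~5500 um^2 with ~25% spread, a 3 um endomysial band,
#' and 30% type II fibers, rendered at 0.5 um/pixel.
#'
#' @param roi_width_um,roi_height_um ROI size (um).
#' @param pixel_size_um pixel size (um/px).
#' @param target_mean_fiber_area_um2 mean fiber polygon area aimed for (um^2).
#' @param fiber_area_cv dimensionless spread of fiber areas; drives the
#'   lattice-site jitter (0 gives a perfectly regular tessellation).
#' @param endomysium_thickness_um generative band width t between adjacent
#'   fiber polygons (um); each Voronoi cell is inset by t/2.
#' @param boundary_width_um width of the rendered basement-membrane line,
#'   drawn outward from each fiber polygon into the band. `NA` (default)
#'   selects 0.75 * t, clamped to [t/2, t] so that adjacent lines tile the
#'   band without entering fiber interiors.
#' @param type2_fraction proportion of type II (fast) fibers in [0, 1].
#' @param type_clustering spatial same-type grouping strength (>= 0; 0 means
#'   independent random type assignment).
#' @param noise_sd additive Gaussian intensity noise (on the [0, 1] scale).
#' @param lattice `"hex"` (default) or `"square"`; the square lattice with
#'   `fiber_area_cv = 0` is the closed-form "grid mode".
#' @param min_fiber_area_um2 border slivers whose rasterization falls below
#'   this area are excluded from the fiber ground truth (a few pixels; such
#'   fragments are below any sensible detection area). Their basement
#'   membrane is still rendered.
#' @param seed integer seed; identical seeds give bit-identical mosaics.
#' @return object of class `mosaic_config`.
#' @export
mosaic_config <- function(roi_width_um = 750, roi_height_um = 750,
                          pixel_size_um = 0.5,
                          target_mean_fiber_area_um2 = 5500,
                          fiber_area_cv = 0.25,
                          endomysium_thickness_um = 3,
                          boundary_width_um = NA_real_,
                          type2_fraction = 0.3,
                          type_clustering = 0,
                          noise_sd = 0.02,
                          lattice = c("hex", "square"),
                          min_fiber_area_um2 = 10,
                          seed = 1L) {
  lattice <- match.arg(lattice)
  stopifnot(roi_width_um > 0, roi_height_um > 0, pixel_size_um > 0,
            target_mean_fiber_area_um2 > 0, fiber_area_cv >= 0,
            endomysium_thickness_um > 0, type2_fraction >= 0,
            type2_fraction <= 1, type_clustering >= 0, noise_sd >= 0)
  if (endomysium_thickness_um >= sqrt(target_mean_fiber_area_um2))
    stop("endomysium_thickness_um must be smaller than sqrt(target mean fiber area)")
  t <- endomysium_thickness_um
  if (is.na(boundary_width_um)) boundary_width_um <- 0.75 * t
  if (boundary_width_um <= 0 || boundary_width_um > t)
    stop("boundary_width_um must lie in (0, endomysium_thickness_um]")
  if (boundary_width_um < t / 2)
    warning("boundary_width_um < t/2 leaves an unstained mid-band corridor; ",
            "segmentation then relies on the background-component rule")
  structure(list(
    roi_width_um = roi_width_um, roi_height_um = roi_height_um,
    pixel_size_um = pixel_size_um,
    target_mean_fiber_area_um2 = target_mean_fiber_area_um2,
    fiber_area_cv = fiber_area_cv,
    endomysium_thickness_um = t,
    boundary_width_um = boundary_width_um,
    type2_fraction = type2_fraction,
    type_clustering = type_clustering,
    noise_sd = noise_sd, lattice = lattice,
    min_fiber_area_um2 = min_fiber_area_um2,
    seed = as.integer(seed)
  ), class = "mosaic_config")
}

# lattice spacing such that the inset cell area hits the target fiber area:
# hexagonal cell of spacing a has inradius a/2, inset by t/2 scales the
# hexagon to inradius (a - t)/2 with area 2*sqrt(3)*rho^2; square cells give
# side (a - t).
lattice_spacing <- function(config) {
  A <- config$target_mean_fiber_area_um2
  t <- config$endomysium_thickness_um
  if (config$lattice == "hex") t + 2 * sqrt(A / (2 * sqrt(3))) else t + sqrt(A)
}

# The site pattern is centred in the ROI (so that commensurate square
# lattices reproduce closed-form grid geometries exactly) and extended three
# periods beyond every border so that all cells reaching the ROI are bounded.
lattice_sites <- function(config, a) {
  W <- config$roi_width_um; H <- config$roi_height_um
  if (config$lattice == "square") {
    kx <- max(1L, round(W / a)); ky <- max(1L, round(H / a))
    x0 <- W / 2 - (kx - 1) * a / 2
    y0 <- H / 2 - (ky - 1) * a / 2
    g <- expand.grid(x = x0 + (-3:(kx + 2)) * a,
                     y = y0 + (-3:(ky + 2)) * a)
  } else {
    dy <- a * sqrt(3) / 2
    kx <- max(1L, round(W / a)); ky <- max(1L, round(H / dy))
    x0 <- W / 2 - (kx - 1) * a / 2
    y0 <- H / 2 - (ky - 1) * dy / 2
    rows <- lapply(-3:(ky + 2), function(r) {
      off <- if (r %% 2 == 0) 0 else a / 2
      cbind(x = x0 + off + (-3:(kx + 2)) * a, y = y0 + r * dy)
    })
    g <- as.data.frame(do.call(rbind, rows))
  }
  as.matrix(g[, c("x", "y")])
}

# Kawasaki-style swap dynamics: preserves the type composition exactly while
# increasing same-type spatial contiguity; strength J = type_clustering,
# fixed 20 sweeps.
potts_cluster_types <- function(types, edges, J, sweeps = 20L) {
  n <- length(types)
  if (J <= 0 || n < 2 || nrow(edges) == 0) return(types)
  if (length(unique(types)) < 2) return(types)
  nb <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  unlike <- function(i, ty) sum(ty[nb[[i]]] != ty[i])
  for (s in seq_len(sweeps)) {
    ii <- sample.int(n, n, replace = TRUE)
    jj <- sample.int(n, n, replace = TRUE)
    for (k in seq_len(n)) {
      i <- ii[k]; j <- jj[k]
      if (types[i] == types[j]) next
      e0 <- unlike(i, types) + unlike(j, types)
      ty2 <- types; ty2[i] <- types[j]; ty2[j] <- types[i]
      e1 <- unlike(i, ty2) + unlike(j, ty2)
      if (e1 <= e0 || stats::runif(1) < exp(-J * (e1 - e0))) types <- ty2
    }
  }
  types
}

quantize16 <- function(img) round(pmin(pmax(img, 0), 1) * 65535) / 65535

#' Generate a ground-truthed muscle fiber mosaic
#'
#' Lays out lattice sites (perturbed by Gaussian jitter proportional to
#' `fiber_area_cv`), computes their Voronoi tessellation, insets every cell by
#' half the endomysial thickness to create an inter-fiber band, clips to the
#' ROI (clipped fibers are flagged trimmed), assigns fiber types, rasterizes
#' a label image and endomysium mask, and renders the two staining
#' modalities: a bright basement-membrane line of `boundary_width_um` drawn
#' outward from each fiber polygon (boundary modality) and a bright
#' endomysial band with dark fiber interiors (fill modality), both with
#' additive Gaussian noise and 16-bit quantization.
#'
#' @param config a [mosaic_config()].
#' @return object of class `muscle_mosaic` with fields `fiber_polygons`
#'   (list of CCW vertex matrices, um), `fiber_types` ("I"/"II"),
#'   `trimmed_flags`, `fiber_areas_um2`, `fiber_perimeters_um`, `adjacency`
#'   (two-column edge matrix of fibers sharing an endomysial boundary),
#'   `fiber_label_image` (integer matrix, rows = y), `endomysium_mask`
#'   (logical matrix), `boundary_image`, `fill_image` (numeric in [0, 1]),
#'   `true_mean_fiber_area_um2` (total fiber area over the trimmed-corrected
#'   count), `true_thickness_um`, and `roi`.
#' @export
generate_mosaic <- function(config) {
  stopifnot(inherits(config, "mosaic_config"))
  a <- lattice_spacing(config)
  t <- config$endomysium_thickness_um
  if (t >= a) stop("endomysial thickness must be smaller than the lattice spacing")
  roi <- roi_geometry(config$roi_width_um, config$roi_height_um,
                      config$pixel_size_um)
  withr::with_seed(config$seed, {
    sites <- lattice_sites(config, a)
    if (config$fiber_area_cv > 0) {
      jit <- 0.8 * config$fiber_area_cv * a
      sites <- sites + matrix(stats::rnorm(length(sites), sd = jit),
                              ncol = 2)
    }
    W <- roi$width_um; H <- roi$height_um
    m <- 3 * a
    bound <- cbind(c(-m, W + m, W + m, -m), c(-m, -m, H + m, H + m))
    # only sites whose cell can reach the ROI matter
    cand <- which(sites[, 1] > -2 * a & sites[, 1] < W + 2 * a &
                  sites[, 2] > -2 * a & sites[, 2] < H + 2 * a)
    polys <- list(); site_of <- integer(0); nb_sites <- list()
    trimmed <- logical(0)
    px <- roi$pixel_size_um
    eps <- 1e-7
    for (i in cand) {
      vc <- voronoi_cell(i, sites, bound)
      if (nrow(vc$cell) < 3) next
      fib <- offset_convex(vc$cell, t / 2)
      if (nrow(fib) < 3) next
      clipped <- clip_rect(fib, W, H)
      if (nrow(clipped) < 3 || poly_area(clipped) <= 0) next
      # trimmed = the ROI boundary actually cut fiber area away (a fiber
      # sitting flush against the border without losing area is complete)
      was_cut <- poly_area(clipped) < poly_area(fib) - 1e-6
      polys[[length(polys) + 1L]] <- clipped
      site_of <- c(site_of, i)
      nb_sites[[length(nb_sites) + 1L]] <- vc$neighbors
      trimmed <- c(trimmed, was_cut)
    }
    # rasterize; the basement membrane is rendered around every cell, but
    # sub-resolution border slivers are excluded from the fiber ground truth
    # (their unstained interiors are below any sensible detection area)
    lab <- matrix(0L, roi$ny, roi$nx)
    keep <- logical(length(polys)); pxl <- vector("list", length(polys))
    for (k in seq_along(polys)) {
      rc <- rasterize_convex(polys[[k]], roi$nx, roi$ny, px)
      pxl[[k]] <- rc
      keep[k] <- nrow(rc) * px^2 >= config$min_fiber_area_um2
    }
    all_polys <- polys
    polys <- polys[keep]; site_of <- site_of[keep]
    nb_sites <- nb_sites[keep]; trimmed <- trimmed[keep]
    pxl_all <- pxl; pxl <- pxl[keep]
    n <- length(polys)
    if (n < 4) stop("configuration yields fewer than 4 fibers")
    for (k in seq_len(n)) lab[pxl[[k]]] <- k
    fiber_of_site <- integer(nrow(sites)); fiber_of_site[site_of] <- seq_len(n)
    edges <- do.call(rbind, lapply(seq_len(n), function(k) {
      j <- fiber_of_site[nb_sites[[k]]]
      j <- j[j > k]
      if (length(j)) cbind(k, j) else NULL
    }))
    if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
    colnames(edges) <- c("from", "to")
    types <- ifelse(stats::runif(n) < config$type2_fraction, "II", "I")
    if (config$type2_fraction <= 0) types <- rep("I", n)
    if (config$type2_fraction >= 1) types <- rep("II", n)
    types <- potts_cluster_types(types, edges, config$type_clustering)
    areas <- vapply(polys, poly_area, 0)
    perims <- vapply(polys, poly_perimeter, 0)
    # render boundary modality: membrane line drawn outward into the band,
    # around every cell (including ground-truth-excluded slivers)
    bnd <- matrix(FALSE, roi$ny, roi$nx)
    w <- config$boundary_width_um
    interior <- matrix(FALSE, roi$ny, roi$nx)
    for (rc in pxl_all) interior[rc] <- TRUE
    for (k in seq_along(all_polys)) {
      rc <- rasterize_convex(offset_convex(all_polys[[k]], -w),
                             roi$nx, roi$ny, px)
      bnd[rc] <- TRUE
    }
    bnd[interior] <- FALSE
    boundary_img <- matrix(0.1, roi$ny, roi$nx)
    boundary_img[bnd] <- 0.8
    fill_img <- matrix(0.8, roi$ny, roi$nx)   # endomysium bright
    fill_img[interior] <- 0.1                 # fiber interiors dark
    if (config$noise_sd > 0) {
      boundary_img <- boundary_img +
        stats::rnorm(length(boundary_img), sd = config$noise_sd)
      fill_img <- fill_img +
        stats::rnorm(length(fill_img), sd = config$noise_sd)
    }
    boundary_img <- quantize16(boundary_img)
    fill_img <- quantize16(fill_img)
    n_t <- sum(trimmed)
    structure(list(
      config = config, roi = roi,
      fiber_polygons = polys, fiber_types = types,
      trimmed_flags = trimmed,
      fiber_areas_um2 = areas, fiber_perimeters_um = perims,
      adjacency = edges,
      fiber_label_image = lab,
      endomysium_mask = lab == 0L,
      boundary_image = boundary_img, fill_image = fill_img,
      true_total_fiber_area_um2 = sum(areas),
      true_total_fiber_perimeter_um = sum(perims),
      true_mean_fiber_area_um2 = sum(areas) / (n - n_t / 2),
      true_thickness_um = t
    ), class = "muscle_mosaic")
  })
}

#' @export
print.muscle_mosaic <- function(x, ...) {
  cat(sprintf(
    "muscle_mosaic: %d fibers (%d trimmed), ROI %g x %g um at %g um/px\n",
    length(x$fiber_polygons), sum(x$trimmed_flags),
    x$roi$width_um, x$roi$height_um, x$roi$pixel_size_um))
  cat(sprintf("  true mean fiber area %.1f um^2, band thickness %g um\n",
              x$true_mean_fiber_area_um2, x$true_thickness_um))
  invisible(x)
}
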