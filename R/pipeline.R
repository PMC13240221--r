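# Pipeline commands tying the stages together with on-disk artifacts:
# simulate (mosaic + ground truth), measure (segmentation + morphometry),
# cohort (group statistics + method agreement). Every output directory gets
# a JSON sidecar with the resolved configuration, seed, and a content hash.

# FNV-1a 32-bit hash of a character string (hex); cheap content fingerprint.
# 32-bit arithmetic is emulated in doubles (xor on the low byte only, since
# FNV xors single input bytes; multiplication split into 16-bit halves to
# stay inside the 2^53 exact-integer range).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261  # 0x811c9dc5
  m <- 16777619    # 0x01000193
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * m) %% 65536) * 65536 + lo * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_run_info <- function(out_dir, config, extra = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  info <- c(list(config = unclass(config),
                 config_hash = fnv1a32(as.character(cfg_json)),
                 seed = config$seed),
            extra)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Simulate a mosaic and write all artifacts
#'
#' Writes `boundary.tif`, `fill.tif`, `labels.tif` (16-bit grayscale),
#' `ground_truth.json` (fiber polygons in micrometre coordinates, types,
#' trimmed flags, scalar truths), `fibers.csv`, and a `run_info.json`
#' sidecar carrying the resolved configuration, its hash, and the seed.
#'
#' @param config a [mosaic_config()].
#' @param out_dir output directory (created if missing).
#' @return the `muscle_mosaic`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "mosaic_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mos <- generate_mosaic(config)
  tiff::writeTIFF(mos$boundary_image, file.path(out_dir, "boundary.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(mos$fill_image, file.path(out_dir, "fill.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(mos$fiber_label_image / 65535,
                  file.path(out_dir, "labels.tif"), bits.per.sample = 16)
  gt <- list(
    fiber_polygons = lapply(mos$fiber_polygons, function(p)
      list(x = p[, 1], y = p[, 2])),
    fiber_types = mos$fiber_types,
    trimmed_flags = mos$trimmed_flags,
    true_mean_fiber_area_um2 = mos$true_mean_fiber_area_um2,
    true_total_fiber_area_um2 = mos$true_total_fiber_area_um2,
    true_total_fiber_perimeter_um = mos$true_total_fiber_perimeter_um,
    true_thickness_um = mos$true_thickness_um,
    roi = unclass(mos$roi))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(
    label = seq_along(mos$fiber_polygons),
    area_um2 = mos$fiber_areas_um2,
    perimeter_um = mos$fiber_perimeters_um,
    fiber_type = mos$fiber_types,
    trimmed = mos$trimmed_flags),
    file.path(out_dir, "fibers.csv"), row.names = FALSE)
  write_run_info(out_dir, config)
  invisible(mos)
}

#' Measure a mosaic (or a simulation directory) in both staining variants
#'
#' Runs boundary-stain segmentation and fill-stain binarization and
#' assembles a [section_morphometry()] row per variant. Manual counting of
#' total and trimmed fibers for the fill variant is emulated from the
#' boundary-variant label image.
#'
#' @param input a `muscle_mosaic` or a directory written by
#'   [run_simulate()].
#' @param out_dir optional output directory for `morphometry.csv` and
#'   `counts.json`.
#' @param threshold `"auto"` or fixed threshold for both stains.
#' @return data frame with one row per variant (see
#'   [as.data.frame.section_morphometry()]).
#' @export
run_measure <- function(input, out_dir = NULL, threshold = "auto") {
  if (is.character(input)) {
    if (!dir.exists(input)) stop("no such input directory: ", input)
    info <- jsonlite::read_json(file.path(input, "run_info.json"))
    cfg <- info$config
    roi <- roi_geometry(cfg$roi_width_um, cfg$roi_height_um,
                        cfg$pixel_size_um)
    boundary <- tiff::readTIFF(file.path(input, "boundary.tif"))
    fill <- tiff::readTIFF(file.path(input, "fill.tif"))
  } else {
    stopifnot(inherits(input, "muscle_mosaic"))
    roi <- input$roi
    boundary <- input$boundary_image
    fill <- input$fill_image
  }
  seg <- segment_boundary_stain(boundary, roi, threshold = threshold)
  sm_b <- section_morphometry(roi, fibers = seg$fibers,
                              variant = "boundary_stain")
  counts <- binarize_fill_stain(fill, roi, threshold = threshold)
  mc <- count_fibers_manual_emulation(seg$label_image)
  sm_f <- section_morphometry(roi, counts = counts,
                              n_total = mc$n_total,
                              n_trimmed = mc$n_trimmed,
                              variant = "fill_square_approx")
  out <- rbind(as.data.frame(sm_b), as.data.frame(sm_f))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(binary_counts = unclass(counts), manual_counts = mc),
      file.path(out_dir, "counts.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate per-subject section morphometry for a cohort
#'
#' Draws subject-level values of the four headline parameters from
#' lognormal distributions whose baselines reproduce plausible soleus
#' values (mean fiber area ~5026 um^2 with CV 0.22, endomysium area per
#' fiber ~777 um^2 with CV 0.135, band thickness ~3 um), with optional
#' per-group fold changes on selected parameters.
#'
#' @param records cohort data frame ([load_cohort_table()]).
#' @param fold_changes named list: per group, a named numeric vector of
#'   fold changes on `mean_fiber_area_um2`, `mean_endomysium_thickness_um`
#'   or `endo_area_per_fiber_um2`.
#' @param baseline named list of baseline means and CVs.
#' @param variant label stored in the `variant` column.
#' @param seed integer seed.
#' @return data frame: subject_id, group, variant, the four parameters.
#' @export
simulate_cohort_morphometry <- function(records, fold_changes = list(),
                                        baseline = list(
                                          mean_fiber_area_um2 = 5026,
                                          area_cv = 0.22,
                                          mean_endomysium_thickness_um = 3,
                                          thickness_cv = 0.2,
                                          endo_area_per_fiber_um2 = 777,
                                          epf_cv = 0.135),
                                        variant = "boundary_stain",
                                        seed = 1L) {
  n <- nrow(records)
  rln <- function(mu, cv, k) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(k, log(mu) - sdlog^2 / 2, sdlog)
  }
  withr::with_seed(seed, {
    abar <- rln(baseline$mean_fiber_area_um2, baseline$area_cv, n)
    tbar <- rln(baseline$mean_endomysium_thickness_um,
                baseline$thickness_cv, n)
    epf <- rln(baseline$endo_area_per_fiber_um2, baseline$epf_cv, n)
    for (g in names(fold_changes)) {
      sel <- records$group == g
      fc <- fold_changes[[g]]
      if ("mean_fiber_area_um2" %in% names(fc))
        abar[sel] <- abar[sel] * fc[["mean_fiber_area_um2"]]
      if ("mean_endomysium_thickness_um" %in% names(fc))
        tbar[sel] <- tbar[sel] * fc[["mean_endomysium_thickness_um"]]
      if ("endo_area_per_fiber_um2" %in% names(fc))
        epf[sel] <- epf[sel] * fc[["endo_area_per_fiber_um2"]]
    }
    data.frame(subject_id = records$subject_id, group = records$group,
               variant = variant,
               mean_fiber_area_um2 = abar,
               mean_endomysium_thickness_um = tbar,
               endo_to_fiber_area_ratio = epf / abar,
               endo_area_per_fiber_um2 = epf)
  })
}

COHORT_PARAMETERS <- c("mean_fiber_area_um2", "mean_endomysium_thickness_um",
                       "endo_to_fiber_area_ratio", "endo_area_per_fiber_um2")

#' Cohort-level group comparisons and method agreement
#'
#' Joins per-subject morphometry with the cohort table, optionally
#' restricts to the diagnosis-adjusted cohort, runs the normality-gated
#' two-group comparison for every group pair and parameter within each
#' variant, and -- when two variants are present -- Bland-Altman agreement
#' between them on mean fiber area and endomysium area per fiber.
#'
#' @param morphometry data frame with columns `subject_id`, `variant`, and
#'   the four parameters (see [simulate_cohort_morphometry()]).
#' @param records cohort data frame.
#' @param adjusted drop biopsies with distinct myopathological diagnoses
#'   first.
#' @param parameters parameter columns to compare.
#' @return list with `comparisons` (parameter, variant, group pair,
#'   test_used, statistic, p) and `bland_altman` (parameter, method pair,
#'   bias, limits, slope) data frames, plus `group_sizes`.
#' @export
run_cohort <- function(morphometry, records, adjusted = FALSE,
                       parameters = COHORT_PARAMETERS) {
  if (adjusted) records <- filter_adjusted_cohort(records)
  dat <- merge(morphometry, records[, c("subject_id", "group")],
               by = "subject_id", suffixes = c("", ".cohort"))
  if (nrow(dat) == 0) stop("no overlap between morphometry and cohort table")
  dat$group <- dat$group.cohort %||% dat$group
  groups <- intersect(COHORT_GROUPS, unique(dat$group))
  comp <- list()
  if (length(groups) < 2) {
    warning("fewer than 2 groups present; no comparisons")
  } else {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (v in unique(dat$variant)) for (p in parameters) for (pr in pairs) {
      x <- dat[dat$variant == v & dat$group == pr[1], p]
      y <- dat[dat$variant == v & dat$group == pr[2], p]
      if (length(x) < 3 || length(y) < 3) next
      r <- suppressWarnings(select_and_run_test(x, y))
      comp[[length(comp) + 1L]] <- data.frame(
        parameter = p, variant = v,
        group_1 = pr[1], group_2 = pr[2],
        n_1 = length(x), n_2 = length(y),
        test_used = r$test_used, statistic = r$statistic,
        p_value = r$p_value)
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(parameter = character(0))
  ba <- list()
  variants <- unique(dat$variant)
  if (length(variants) >= 2) {
    vp <- utils::combn(variants, 2, simplify = FALSE)
    for (pr in vp) for (p in intersect(c("mean_fiber_area_um2",
                                         "endo_area_per_fiber_um2"),
                                       parameters)) {
      a <- dat[dat$variant == pr[1], c("subject_id", p)]
      b <- dat[dat$variant == pr[2], c("subject_id", p)]
      jo <- merge(a, b, by = "subject_id")
      if (nrow(jo) < 3) next
      r <- bland_altman(jo[[paste0(p, ".x")]], jo[[paste0(p, ".y")]])
      ba[[length(ba) + 1L]] <- data.frame(
        parameter = p, method_1 = pr[1], method_2 = pr[2],
        n = r$n, bias = r$bias, loa_low = r$loa_low,
        loa_high = r$loa_high, slope = r$proportional_bias_slope,
        slope_p = r$slope_p)
    }
  }
  list(comparisons = comparisons,
       bland_altman = if (length(ba)) do.call(rbind, ba) else
         data.frame(parameter = character(0)),
       group_sizes = table(dat$group[dat$variant == dat$variant[1]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
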