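# Synthetic protein-abundance matrices with group structure and
# detection-limit (missing-not-at-random) censoring, including an optional
# planted one-group-absent protein mimicking a presence/absence pattern.

#' Configuration for the abundance-matrix simulator
#'
#' Defaults mirror a four-group muscle-biopsy cohort (12/10/11/10 samples)
#' quantified on the log2 scale.
#'
#' @param n_proteins number of proteins.
#' @param samples_per_group named integer vector of group sizes (the four
#'   groups YUA, YPT, AUA, APT by default).
#' @param effect_fraction fraction of proteins receiving a group-mean shift
#'   in one randomly chosen group.
#' @param effect_size_sd_units size of that shift in within-group SD units.
#' @param detection_limit_quantile global quantile of the value distribution
#'   below which values are censored to missing (MNAR), in [0, 1).
#' @param planted_absence optional list(protein_index, absent_group,
#'   residual_detections) forcing one protein to be undetected in
#'   `absent_group` except for `residual_detections` samples, while being
#'   detected in at least 90\% of samples in every other group.
#' @param seed integer seed.
#' @return object of class `abundance_sim_config`.
#' @export
abundance_sim_config <- function(n_proteins = 1000L,
                                 samples_per_group = c(YUA = 12L, YPT = 10L,
                                                       AUA = 11L, APT = 10L),
                                 effect_fraction = 0,
                                 effect_size_sd_units = 2,
                                 detection_limit_quantile = 0.05,
                                 planted_absence = NULL,
                                 seed = 1L) {
  stopifnot(n_proteins >= 1, all(samples_per_group >= 1),
            effect_fraction >= 0, effect_fraction <= 1,
            detection_limit_quantile >= 0, detection_limit_quantile < 1)
  if (is.null(names(samples_per_group)))
    names(samples_per_group) <- paste0("G", seq_along(samples_per_group))
  if (!is.null(planted_absence)) {
    stopifnot(is.list(planted_absence),
              all(c("protein_index", "absent_group",
                    "residual_detections") %in% names(planted_absence)))
    if (planted_absence$protein_index < 1 ||
        planted_absence$protein_index > n_proteins)
      stop("planted protein index out of range")
    if (!planted_absence$absent_group %in% names(samples_per_group))
      stop("unknown absent_group")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 samples_per_group = samples_per_group,
                 effect_fraction = effect_fraction,
                 effect_size_sd_units = effect_size_sd_units,
                 detection_limit_quantile = detection_limit_quantile,
                 planted_absence = planted_absence,
                 seed = as.integer(seed)),
            class = "abundance_sim_config")
}

#' Generate a synthetic abundance matrix
#'
#' Protein log-abundances are i.i.d. normal around protein-specific means
#' (means ~ N(28, 2.5), within-group SDs ~ U(0.2, 0.6), log2-scale LFQ-like
#' values); `effect_fraction` of proteins receive a mean shift of
#' `effect_size_sd_units` SDs in one random group; values below the global
#' `detection_limit_quantile` of the pooled value distribution are censored
#' to `NA` (missing not at random); the optional planted-absence protein is
#' then forced to the requested detection pattern.
#'
#' @param config an [abundance_sim_config()].
#' @return an [abundance_matrix()]; attributes `effect_proteins` (indices)
#'   and `effect_groups` record the planted effects.
#' @export
generate_abundance_matrix <- function(config) {
  stopifnot(inherits(config, "abundance_sim_config"))
  P <- config$n_proteins
  gs <- config$samples_per_group
  groups <- rep(names(gs), times = gs)
  N <- length(groups)
  withr::with_seed(config$seed, {
    mu <- stats::rnorm(P, 28, 2.5)
    sig <- stats::runif(P, 0.2, 0.6)
    v <- matrix(stats::rnorm(P * N), P, N) * sig + mu
    n_eff <- round(config$effect_fraction * P)
    eff_idx <- if (n_eff > 0) sample.int(P, n_eff) else integer(0)
    eff_grp <- if (n_eff > 0) sample(names(gs), n_eff, replace = TRUE)
               else character(0)
    for (k in seq_along(eff_idx)) {
      cols <- which(groups == eff_grp[k])
      v[eff_idx[k], cols] <- v[eff_idx[k], cols] +
        config$effect_size_sd_units * sig[eff_idx[k]]
    }
    q <- if (config$detection_limit_quantile > 0)
      stats::quantile(v, config$detection_limit_quantile) else -Inf
    v[v < q] <- NA
    pa <- config$planted_absence
    if (!is.null(pa)) {
      i <- pa$protein_index
      cols_abs <- which(groups == pa$absent_group)
      if (pa$residual_detections > length(cols_abs))
        stop("residual_detections exceeds the absent group size")
      det <- sample(cols_abs, pa$residual_detections)
      v[i, setdiff(cols_abs, det)] <- NA
      # residual detections sit just above the detection limit
      lo <- if (is.finite(q)) q else mu[i] - 2 * sig[i]
      v[i, det] <- lo + abs(stats::rnorm(length(det), 0, 0.2 * sig[i]))
      # elsewhere the protein is reliably detected (>= 90% per group)
      for (g in setdiff(names(gs), pa$absent_group)) {
        cols <- which(groups == g)
        need <- ceiling(0.9 * length(cols))
        miss <- cols[is.na(v[i, cols])]
        n_restore <- max(0L, need - (length(cols) - length(miss)))
        if (n_restore > 0) {
          res <- utils::head(miss, n_restore)
          v[i, res] <- mu[i] + abs(stats::rnorm(length(res), 0, sig[i]))
        }
      }
    }
    rownames(v) <- sprintf("P%04d", seq_len(P))
    colnames(v) <- paste0(groups, "_", stats::ave(seq_len(N), groups,
                                                  FUN = seq_along))
    out <- abundance_matrix(v, groups)
    attr(out, "effect_proteins") <- eff_idx
    attr(out, "effect_groups") <- eff_grp
    out
  })
}
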