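# Proteomics screening downstream of quantification: valid-value filtering,
# left-shifted Gaussian imputation, permutation-FDR ANOVA and pairwise Welch
# tests, Venn partitioning, and the detection-pattern presence/absence
# screen. Abundances are log-scale, proteins x samples, with NA marking a
# value below the detection limit.

#' Construct an abundance matrix container
#'
#' @param values numeric matrix, rows proteins, columns samples; `NA` marks
#'   missing (not detected) values. Row and column names are used as protein
#'   and sample identifiers.
#' @param groups character/factor of length `ncol(values)` assigning each
#'   sample to one group.
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (length(groups) != ncol(values))
    stop("one group per sample required")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  structure(list(values = values,
                 groups = as.character(groups),
                 protein_ids = rownames(values),
                 sample_ids = colnames(values)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  print(table(x$groups))
  invisible(x)
}

group_index <- function(mat) split(seq_along(mat$groups), mat$groups)

#' Filter proteins by valid values per group
#'
#' Keeps a protein when at least one group quantifies it in at least
#' `threshold` of its samples; the fraction comparison is exact, so 7 of 10
#' passes a 0.7 threshold while 7 of 11 does not.
#'
#' @param mat an [abundance_matrix()].
#' @param threshold minimal within-group valid-value fraction.
#' @return filtered `abundance_matrix` (possibly with zero rows).
#' @export
filter_valid_values <- function(mat, threshold = 0.7) {
  stopifnot(inherits(mat, "abundance_matrix"))
  gi <- group_index(mat)
  if (any(lengths(gi) == 0)) stop("empty group")
  frac <- sapply(gi, function(ix)
    rowMeans(!is.na(mat$values[, ix, drop = FALSE])))
  keep <- apply(frac >= threshold, 1, any)
  abundance_matrix(mat$values[keep, , drop = FALSE], mat$groups)
}

#' Impute missing values from a left-shifted Gaussian
#'
#' Each missing entry is drawn from a normal distribution centred
#' `downshift` sample standard deviations below the sample mean with width
#' `width` sample SDs, computed per sample from its observed values -- the
#' usual model for abundances missing because they fall below the detection
#' limit.
#'
#' @param mat an [abundance_matrix()].
#' @param downshift centre shift in sample-SD units.
#' @param width imputation width in sample-SD units.
#' @param seed integer seed.
#' @return complete `abundance_matrix`.
#' @export
impute_missing <- function(mat, downshift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(inherits(mat, "abundance_matrix"))
  v <- mat$values
  withr::with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      obs <- v[!miss, j]
      if (length(obs) < 2)
        stop("sample ", mat$sample_ids[j],
             " has fewer than 2 observed values")
      mu <- mean(obs); s <- stats::sd(obs)
      v[miss, j] <- stats::rnorm(sum(miss), mu - downshift * s, width * s)
    }
  })
  abundance_matrix(v, mat$groups)
}

# moderated one-way F statistics for every row of a complete matrix;
# s0 is added to the pooled within-group standard deviation (SAM-style
# fudge; 0 gives the plain F statistic)
row_f_stat <- function(v, groups, s0 = 0) {
  gl <- unique(groups)
  k <- length(gl); n <- ncol(v)
  gs <- vapply(gl, function(g) sum(groups == g), 0)
  M <- vapply(gl, function(g)
    rowMeans(v[, groups == g, drop = FALSE]), numeric(nrow(v)))
  M <- matrix(M, nrow = nrow(v))
  grand <- rowMeans(v)
  ss_between <- rowSums(sweep(M, 2, gs, "*") * M) - n * grand^2
  ss_total <- rowSums(v^2) - n * grand^2
  ss_within <- pmax(ss_total - ss_between, 0)
  ms_b <- ss_between / (k - 1)
  sw <- sqrt(ss_within / (n - k))
  ms_w_mod <- (sw + s0)^2
  f <- ms_b / ms_w_mod
  f[!is.finite(f)] <- 0
  f
}

# Welch t statistics for every row, two groups
row_welch_t <- function(v, groups, pair) {
  a <- v[, groups == pair[1], drop = FALSE]
  b <- v[, groups == pair[2], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  (rowMeans(a) - rowMeans(b)) / sqrt(va / na + vb / nb)
}

# permutation-based FDR: given observed statistics and a matrix of permuted
# statistics (rows proteins, columns permutations), computes for each
# protein the estimated FDR at its own threshold and the largest
# significant set with estimated FDR <= level
perm_fdr <- function(obs, perm, level) {
  ord <- order(obs, decreasing = TRUE)
  sorted <- obs[ord]
  pooled <- sort(as.vector(perm))
  B <- ncol(perm)
  # mean permutation count of statistics >= c, for c = each observed value
  exceed <- length(pooled) -
    findInterval(sorted - 1e-12, pooled)  # count of pooled >= sorted[i]
  fdr_at <- (exceed / B) / seq_along(sorted)
  q <- rev(cummin(rev(pmin(fdr_at, 1))))
  n_sig <- if (any(q <= level)) max(which(q <= level)) else 0L
  sig <- logical(length(obs))
  if (n_sig > 0) sig[ord[seq_len(n_sig)]] <- TRUE
  qv <- numeric(length(obs)); qv[ord] <- q
  list(significant = sig, q_value = qv, n_significant = n_sig)
}

#' One-way ANOVA with permutation-based FDR
#'
#' Computes a one-way F statistic per protein across the sample groups
#' (optionally moderated by adding `s0` to the pooled within-group SD) and
#' estimates the false discovery rate by permuting the group labels --
#' identically across proteins in each permutation round. For a threshold
#' c, FDR(c) is the mean permutation count of statistics at or above c
#' divided by the observed count; the significant set is the largest set
#' with estimated FDR at or below `fdr_level`.
#'
#' @param mat complete (imputed) [abundance_matrix()].
#' @param n_permutations number of label permutations (warned below 100).
#' @param fdr_level target FDR.
#' @param s0 SAM-style variance fudge added to the pooled SD.
#' @param seed integer seed for the permutations.
#' @return data frame: `protein_id`, `F_statistic`, `q_value`,
#'   `significant`.
#' @export
anova_permutation_fdr <- function(mat, n_permutations = 1000L,
                                  fdr_level = 0.05, s0 = 0, seed = 1L) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (anyNA(mat$values)) stop("matrix must be complete (impute first)")
  if (n_permutations < 100) warning("fewer than 100 permutations")
  gs <- table(mat$groups)
  if (length(gs) < 2 || any(gs < 2))
    stop("need at least 2 groups with at least 2 samples each")
  v <- mat$values
  obs <- row_f_stat(v, mat$groups, s0)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b)
      row_f_stat(v, sample(mat$groups), s0), numeric(nrow(v)))
  })
  if (is.null(dim(perm))) perm <- matrix(perm, nrow = nrow(v))
  fd <- perm_fdr(obs, perm, fdr_level)
  data.frame(protein_id = mat$protein_ids, F_statistic = obs,
             q_value = fd$q_value, significant = fd$significant,
             row.names = NULL)
}

#' Pairwise Welch's t-tests with permutation-based FDR
#'
#' Welch t statistic per protein for one pair of groups; the FDR of the
#' two-sided test (on |t|) is estimated from group-label permutations
#' within the two groups, as in [anova_permutation_fdr()].
#'
#' @param mat complete [abundance_matrix()].
#' @param group_pair character vector of the two group labels to compare.
#' @inheritParams anova_permutation_fdr
#' @return data frame: `protein_id`, `t_statistic`, `q_value`,
#'   `significant`.
#' @export
pairwise_welch_fdr <- function(mat, group_pair, n_permutations = 1000L,
                               fdr_level = 0.05, seed = 1L) {
  stopifnot(inherits(mat, "abundance_matrix"), length(group_pair) == 2)
  if (anyNA(mat$values)) stop("matrix must be complete (impute first)")
  sel <- mat$groups %in% group_pair
  v <- mat$values[, sel, drop = FALSE]
  g <- mat$groups[sel]
  if (min(table(g)) < 2) stop("each group needs at least 2 samples")
  obs <- abs(row_welch_t(v, g, group_pair))
  obs[!is.finite(obs)] <- 0
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      tb <- abs(row_welch_t(v, sample(g), group_pair))
      tb[!is.finite(tb)] <- 0
      tb
    }, numeric(nrow(v)))
  })
  if (is.null(dim(perm))) perm <- matrix(perm, nrow = nrow(v))
  fd <- perm_fdr(obs, perm, fdr_level)
  data.frame(protein_id = mat$protein_ids, t_statistic = obs,
             q_value = fd$q_value, significant = fd$significant,
             row.names = NULL)
}

#' Venn partition of three protein lists
#'
#' @param list_A,list_B,list_C character vectors of protein identifiers.
#' @return list with `sizes` (named integer vector over the 7 regions
#'   `A_only`, `B_only`, `C_only`, `AB_only`, `AC_only`, `BC_only`, `ABC`)
#'   and `members` (the identifiers in each region).
#' @export
venn_partition <- function(list_A, list_B, list_C = character(0)) {
  A <- unique(as.character(list_A)); B <- unique(as.character(list_B))
  C <- unique(as.character(list_C))
  u <- union(union(A, B), C)
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  regions <- list(
    A_only = u[inA & !inB & !inC],
    B_only = u[!inA & inB & !inC],
    C_only = u[!inA & !inB & inC],
    AB_only = u[inA & inB & !inC],
    AC_only = u[inA & !inB & inC],
    BC_only = u[!inA & inB & inC],
    ABC = u[inA & inB & inC])
  list(sizes = vapply(regions, length, 0L), members = regions)
}

#' Presence/absence detection-pattern screen
#'
#' Flags proteins that are essentially undetected in one group while being
#' reliably detected in all others: the detection fraction in the flagged
#' group is at most `f_low` and at least `f_high` in every other group.
#' This screen runs on the pre-imputation missingness pattern -- imputation
#' would erase exactly the signal it looks for.
#'
#' @param mat an [abundance_matrix()] with `NA` marking non-detection.
#' @param f_low maximal detection fraction in the absent group.
#' @param f_high minimal detection fraction in every other group.
#' @return data frame of candidates: `protein_id`, `absent_group`, one
#'   `frac_<group>` column per group.
#' @export
absence_screen <- function(mat, f_low = 0.25, f_high = 0.8) {
  stopifnot(inherits(mat, "abundance_matrix"), f_low < f_high)
  gi <- group_index(mat)
  frac <- sapply(gi, function(ix)
    rowMeans(!is.na(mat$values[, ix, drop = FALSE])))
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1,
                                         dimnames = list(NULL, names(gi)))
  hits <- do.call(rbind, lapply(seq_len(nrow(frac)), function(i) {
    lows <- which(frac[i, ] <= f_low)
    if (length(lows) != 1) return(NULL)
    if (all(frac[i, -lows] >= f_high)) {
      out <- data.frame(protein_id = mat$protein_ids[i],
                        absent_group = colnames(frac)[lows])
      for (g in colnames(frac)) out[[paste0("frac_", g)]] <- frac[i, g]
      out
    } else NULL
  }))
  if (is.null(hits))
    hits <- data.frame(protein_id = character(0),
                       absent_group = character(0))
  hits
}
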