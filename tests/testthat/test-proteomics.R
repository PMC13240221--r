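# Valid-value filter, imputation, permutation-FDR tests, Venn partition,
# and the presence/absence screen.

four_groups <- function(sizes = c(YUA = 12, YPT = 10, AUA = 11, APT = 10))
  rep(names(sizes), times = sizes)

test_that("valid-value filter applies the exact fraction rule", {
  g <- four_groups()
  v <- matrix(rnorm(3 * 43), 3, 43)
  # protein 1 complete; protein 2: 7/10 valid in YPT only; protein 3: 7/11
  # valid in AUA and fewer elsewhere
  v[2, ] <- NA; v[2, which(g == "YPT")[1:7]] <- 0
  v[3, ] <- NA; v[3, which(g == "AUA")[1:7]] <- 0
  m <- abundance_matrix(v, g)
  kept <- filter_valid_values(m, 0.7)
  expect_equal(kept$protein_ids, c("P1", "P2"))  # 7/10 passes, 7/11 fails
})

test_that("valid-value filter equals a brute-force oracle and is idempotent", {
  g <- four_groups()
  for (s in 1:3) {
    set.seed(s)
    v <- matrix(rnorm(200 * 43), 200, 43)
    v[runif(length(v)) < 0.4] <- NA
    m <- abundance_matrix(v, g)
    kept <- filter_valid_values(m, 0.7)
    oracle <- vapply(seq_len(nrow(v)), function(i) {
      any(vapply(unique(g), function(gr)
        mean(!is.na(v[i, g == gr])) >= 0.7, TRUE))
    }, TRUE)
    expect_equal(kept$protein_ids, paste0("P", which(oracle)))
    again <- filter_valid_values(kept, 0.7)
    expect_identical(again$values, kept$values)
  }
})

test_that("imputation completes the matrix from the left-shifted Gaussian", {
  g <- four_groups()
  set.seed(2)
  v <- matrix(rnorm(2000 * 43, 28, 1), 2000, 43)
  complete <- abundance_matrix(v, g)
  expect_identical(impute_missing(complete, seed = 1)$values,
                   complete$values)
  v[sample(length(v), 20000)] <- NA
  m <- abundance_matrix(v, g)
  imp1 <- impute_missing(m, seed = 9)
  imp2 <- impute_missing(m, seed = 9)
  expect_false(anyNA(imp1$values))
  expect_identical(imp1$values, imp2$values)
  # distributional check on one sample column
  j <- 1
  miss <- is.na(v[, j])
  obs <- v[!miss, j]
  drawn <- imp1$values[miss, j]
  expect_equal(mean(drawn), mean(obs) - 1.8 * sd(obs),
               tolerance = 0.05 * sd(obs) * 3 / sqrt(sum(miss)) + 0.02)
})

test_that("a constant matrix yields no ANOVA discoveries", {
  g <- four_groups()
  m <- abundance_matrix(matrix(5, 50, 43), g)
  res <- anova_permutation_fdr(m, n_permutations = 120, seed = 1)
  expect_equal(sum(res$significant), 0)
})

test_that("planted group effects are recovered at controlled FDR", {
  cfg <- abundance_sim_config(n_proteins = 600, effect_fraction = 0.05,
                              effect_size_sd_units = 2.5,
                              detection_limit_quantile = 0, seed = 21)
  m <- generate_abundance_matrix(cfg)
  res <- anova_permutation_fdr(m, n_permutations = 300, seed = 2)
  eff <- attr(m, "effect_proteins")
  expect_gte(mean(res$significant[eff]), 0.8)
  fp <- sum(res$significant[-eff])
  expect_lte(fp / max(1, sum(res$significant)), 0.15)
})

test_that("pairwise Welch screen finds pair-specific effects only", {
  g <- four_groups()
  set.seed(5)
  v <- matrix(rnorm(400 * 43, 28, 0.5), 400, 43)
  planted <- 1:10
  v[planted, g == "APT"] <- v[planted, g == "APT"] + 2
  m <- abundance_matrix(v, g)
  hit <- pairwise_welch_fdr(m, c("YUA", "APT"), n_permutations = 200,
                            seed = 3)
  expect_gte(mean(hit$significant[planted]), 0.8)
  null_pair <- pairwise_welch_fdr(m, c("YUA", "YPT"),
                                  n_permutations = 200, seed = 3)
  expect_lte(sum(null_pair$significant), 2)
  # identical groups built by copying samples: nothing can be significant
  v2 <- v; v2[, g == "YPT"] <- v2[, g == "YUA"][, 1:10]
  same <- pairwise_welch_fdr(abundance_matrix(v2, g), c("YUA", "YPT"),
                             n_permutations = 120, seed = 1)
  expect_lte(sum(same$significant), 1)
})

test_that("Venn partition is exact set algebra", {
  vp <- venn_partition(letters[1:4], letters[3:6], letters[5:8])
  expect_equal(unname(vp$sizes),
               c(2L, 0L, 2L, 2L, 0L, 2L, 0L))
  dis <- venn_partition("a", "b", "c")
  expect_equal(sum(dis$sizes[c("AB_only", "AC_only", "BC_only", "ABC")]), 0)
  same <- venn_partition(letters[1:3], letters[1:3])
  expect_equal(unname(same$sizes["AB_only"]), 3L)
  # random lists against a brute-force membership table
  set.seed(8)
  A <- sample(letters, 10); B <- sample(letters, 12); C <- sample(letters, 7)
  vp2 <- venn_partition(A, B, C)
  u <- union(union(A, B), C)
  tab <- table(factor(paste0(as.integer(u %in% A), as.integer(u %in% B),
                             as.integer(u %in% C)),
                      levels = c("100", "010", "001", "110", "101",
                                 "011", "111")))
  expect_equal(unname(vp2$sizes), as.vector(tab))
})

test_that("absence screen flags the printed detection pattern uniquely", {
  g <- four_groups()
  set.seed(4)
  v <- matrix(rnorm(100 * 43, 28, 0.5), 100, 43)
  # protein 10: detected 12/12, 9/10, 9/11, 2/10 across the four groups
  v[10, which(g == "YPT")[1]] <- NA
  v[10, which(g == "AUA")[1:2]] <- NA
  v[10, which(g == "APT")[3:10]] <- NA
  m <- abundance_matrix(v, g)
  hits <- absence_screen(m)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$absent_group, "APT")
  expect_equal(hits$frac_APT, 0.2)
  expect_equal(hits$frac_AUA, 9 / 11)
  # fully detected and fully missing proteins are never flagged
  v2 <- v; v2[20, ] <- NA
  expect_false(any(absence_screen(abundance_matrix(v2, g))$protein_id
                   %in% c("P1", "P20")))
})

test_that("the screen runs pre-imputation and imputation cannot change it", {
  cfg <- abundance_sim_config(
    n_proteins = 300, detection_limit_quantile = 0.05,
    planted_absence = list(protein_index = 7, absent_group = "APT",
                           residual_detections = 2), seed = 13)
  m <- generate_abundance_matrix(cfg)
  hits <- absence_screen(m)
  expect_true("P0007" %in% hits$protein_id)
  imp <- impute_missing(filter_valid_values(m), seed = 1)
  expect_false(anyNA(imp$values))  # post-imputation there is no pattern left
})
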