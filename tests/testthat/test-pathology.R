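# Cohort table, diagnosis counting, adjusted cohort, and the diagnostic
# rule cascade.

test_that("the packaged cohort table carries the expected structure", {
  tab <- cohort_fixture()
  expect_equal(nrow(tab), 43)
  expect_equal(as.vector(table(tab$group)[c("YUA", "YPT", "AUA", "APT")]),
               c(12, 10, 11, 10))
  expect_equal(tab$diagnosis[tab$subject_id == "ED5"],
               "unspecific_myositic")
  expect_equal(tab$diagnosis[tab$subject_id == "FP7"],
               "type2_fiber_atrophy")
})

test_that("diagnosis counts match the cohort annotations", {
  dc <- diagnosis_counts(cohort_fixture())
  expect_equal(unname(dc$overall),
               c(26L, 11L, 4L, 1L, 1L))
  expect_equal(unname(dc$normal_per_group), c(10L, 9L, 7L, 0L))
  empty <- diagnosis_counts(cohort_fixture()[0, ])
  expect_true(all(empty$overall == 0L))
})

test_that("the adjusted cohort keeps normal and unspecific biopsies only", {
  tab <- cohort_fixture()
  adj <- filter_adjusted_cohort(tab)
  expect_equal(as.vector(table(adj$group)[c("YUA", "YPT", "AUA", "APT")]),
               c(12, 10, 10, 5))
  expect_equal(nrow(tab) - nrow(adj), 6)  # 4 + 1 + 1 distinct diagnoses
  all_norm <- tab; all_norm$diagnosis <- "normal"
  expect_equal(nrow(filter_adjusted_cohort(all_norm)), 43)
  all_neuro <- tab; all_neuro$diagnosis <- "chronic_neurogenic_atrophy"
  expect_equal(nrow(filter_adjusted_cohort(all_neuro)), 0)
})

test_that("cohort loader rejects malformed tables", {
  tab <- cohort_fixture()
  tmp <- tempfile(fileext = ".csv")
  bad <- tab; bad$subject_id[2] <- bad$subject_id[1]
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_cohort_table(tmp), "duplicate")
  bad2 <- tab; bad2$group[1] <- "XXX"
  write.csv(bad2, tmp, row.names = FALSE)
  expect_error(load_cohort_table(tmp), "unknown group")
  bad3 <- tab; bad3$diagnosis[1] <- "mystery"
  write.csv(bad3, tmp, row.names = FALSE)
  expect_error(load_cohort_table(tmp), "diagnosis")
})

test_that("type groups: planted clusters found, checkerboards dissolve", {
  pop <- generate_pathological_population(100, "neurogenic_grouping",
                                          params = list(group_size = 20),
                                          seed = 1)
  grp <- detect_fiber_type_groups(pop, min_size = 15)
  expect_gte(max(c(0, lengths(grp$II))), 15)
  # strict checkerboard on a square grid: all same-type components singleton
  n <- 64; k <- 8
  types <- ifelse((((seq_len(n) - 1) %/% k) + ((seq_len(n) - 1) %% k))
                  %% 2 == 0, "I", "II")
  edges <- rbind(
    cbind(which(seq_len(n) %% k != 0), which(seq_len(n) %% k != 0) + 1L),
    cbind(seq_len(n - k), seq_len(n - k) + k))
  board <- list(types = types, adjacency = edges)
  grp2 <- detect_fiber_type_groups(board, min_size = 2)
  expect_equal(length(grp2$I), 0)
  expect_equal(length(grp2$II), 0)
})

test_that("group detection equals a brute-force component search", {
  bfs_components <- function(types, edges) {
    n <- length(types)
    nb <- vector("list", n)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      if (types[i] == types[j]) {
        nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
      }
    }
    seen <- logical(n); comps <- list()
    for (s in seq_len(n)) {
      if (seen[s]) next
      q <- s; seen[s] <- TRUE; comp <- integer(0)
      while (length(q)) {
        v <- q[1]; q <- q[-1]; comp <- c(comp, v)
        for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; q <- c(q, w) }
      }
      comps[[length(comps) + 1]] <- sort(comp)
    }
    comps
  }
  for (s in 1:3) {
    pop <- generate_pathological_population(80, "normal", seed = s)
    grp <- detect_fiber_type_groups(pop, min_size = 2)
    found <- c(grp$I, grp$II)
    oracle <- bfs_components(pop$types, pop$adjacency)
    oracle <- Filter(function(m) length(m) >= 2, oracle)
    expect_equal(length(found), length(oracle))
    expect_setequal(vapply(found, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("classification cascade hits each planted diagnosis", {
  neuro <- generate_pathological_population(100, "neurogenic_grouping",
                                            seed = 3)
  expect_equal(classify_biopsy(neuro), "chronic_neurogenic_atrophy")
  # direct construction: 90% of type II at 0.80x the type I mean
  n <- 60
  types <- rep(c("I", "II"), each = n / 2)
  d <- c(rep(60, n / 2), rep(c(48, 60), times = c(27, 3)))
  pop <- list(types = types, min_feret_um = d,
              adjacency = matrix(integer(0), 0, 2))
  expect_equal(classify_biopsy(pop), "type2_fiber_atrophy")
  clean <- list(types = rep(c("I", "II"), 20),
                min_feret_um = rep(60, 40),
                adjacency = cbind(1:39, 2:40),
                n_atrophic_fibers = 0, n_nuclear_clumps = 0,
                n_ragged_red = 0, n_cox_negative = 0,
                frac_centralized_nuclei = 0,
                infiltrate_endomysial = FALSE,
                infiltrate_perimysial = FALSE)
  expect_equal(classify_biopsy(clean), "normal")
  myo <- clean; myo$infiltrate_endomysial <- TRUE
  expect_equal(classify_biopsy(myo), "unspecific_myositic")
  unspec <- clean; unspec$n_nuclear_clumps <- 2
  expect_equal(classify_biopsy(unspec), "unspecific_myopathological")
  centr <- clean; centr$frac_centralized_nuclei <- 0.05
  expect_equal(classify_biopsy(centr), "unspecific_myopathological")
})

test_that("classification is invariant under fiber relabeling", {
  pop <- generate_pathological_population(100, "neurogenic_grouping",
                                          seed = 5)
  d0 <- classify_biopsy(pop)
  set.seed(1)
  perm <- sample(100)
  inv <- integer(100); inv[perm] <- seq_len(100)
  pop2 <- pop
  pop2$types <- pop$types[perm]
  pop2$min_feret_um <- pop$min_feret_um[perm]
  pop2$adjacency <- cbind(inv[pop$adjacency[, 1]], inv[pop$adjacency[, 2]])
  expect_equal(classify_biopsy(pop2), d0)
})

test_that("spurious grouping under random typing stays rare", {
  res <- vapply(1:200, function(s)
    classify_biopsy(generate_pathological_population(100, "normal",
                                                     seed = s)),
    "")
  expect_lt(mean(res == "chronic_neurogenic_atrophy"), 0.10)
  expect_gte(mean(res == "normal"), 0.90)
})
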