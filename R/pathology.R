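# Myopathological evaluation: cohort-table handling, diagnosis counting, the
# diagnosis-adjusted cohort, and the rule-based classification of fiber
# populations (fiber-type grouping, type II fiber atrophy, myositic and
# unspecific changes).

DIAGNOSIS_LEVELS <- c("normal", "unspecific_myopathological",
                      "chronic_neurogenic_atrophy", "type2_fiber_atrophy",
                      "unspecific_myositic")
COHORT_GROUPS <- c("YUA", "YPT", "AUA", "APT")

#' Load a cohort annotation table
#'
#' Reads one biopsy per row: subject ID (two letters and a digit), study
#' group (YUA young unathletic, YPT young power-trained, AUA aged
#' unathletic, APT aged power-trained), free-text myopathological findings,
#' per-stain gradings, and the expert diagnosis. A blank diagnosis cell
#' means normal skeletal muscle. The packaged example table describes a
#' 43-participant cross-sectional cohort (12/10/11/10 per group).
#'
#' @param path CSV file; defaults to the packaged cohort table.
#' @return data frame with a validated `diagnosis` column (one of
#'   `r paste(DIAGNOSIS_LEVELS, collapse = ", ")`).
#' @export
load_cohort_table <- function(path = system.file("extdata",
                                                 "cohort_table.csv",
                                                 package = "myomorph")) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(diagnosis = "character"))
  required <- c("subject_id", "group", "diagnosis")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("cohort table lacks required columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in cohort table: ",
         paste(tab$subject_id[duplicated(tab$subject_id)], collapse = ", "))
  bad <- setdiff(unique(tab$group), COHORT_GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  tab$diagnosis[is.na(tab$diagnosis) | tab$diagnosis == ""] <- "normal"
  bad <- setdiff(unique(tab$diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad))
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  tab
}

#' Diagnosis counts, overall and per group
#'
#' @param records cohort data frame as from [load_cohort_table()].
#' @return list with `overall` (named counts over all diagnosis labels) and
#'   `normal_per_group` (named count of normal biopsies per study group).
#' @export
diagnosis_counts <- function(records) {
  overall <- vapply(DIAGNOSIS_LEVELS,
                    function(d) sum(records$diagnosis == d), 0L)
  per_group <- vapply(COHORT_GROUPS, function(g)
    sum(records$group == g & records$diagnosis == "normal"), 0L)
  list(overall = overall, normal_per_group = per_group)
}

#' Diagnosis-adjusted cohort
#'
#' Restricts the cohort to biopsies that are normal or show only unspecific
#' myopathological changes, dropping the distinct diagnoses (chronic
#' neurogenic atrophy, type II fiber atrophy, myositic changes).
#'
#' @param records cohort data frame.
#' @return the retained subset, same columns.
#' @export
filter_adjusted_cohort <- function(records) {
  records[records$diagnosis %in%
            c("normal", "unspecific_myopathological"), , drop = FALSE]
}

#' Find spatially contiguous same-type fiber groups
#'
#' Fiber-type grouping -- the morphological hallmark of chronic neurogenic
#' atrophy with reinnervation -- is detected as connected components of the
#' subgraph induced by each fiber type on the adjacency graph (fibers are
#' adjacent when they share an endomysial boundary).
#'
#' @param population a `fiber_population` (see
#'   [generate_pathological_population()]) or any list with `types`
#'   ("I"/"II") and `adjacency` (two-column edge matrix).
#' @param min_size minimal group size reported (default 15 fibers).
#' @return list with elements `I` and `II`, each a list of integer vectors
#'   (fiber indices of one group of at least `min_size` fibers).
#' @export
detect_fiber_type_groups <- function(population, min_size = 15L) {
  types <- population$types
  n <- length(types)
  if (n == 0) stop("empty fiber population")
  edges <- population$adjacency
  # keep only edges joining fibers of the same type; components of the
  # resulting graph are the candidate groups (multi-fiber components are
  # same-type by construction)
  if (!is.null(edges) && nrow(edges) > 0) {
    same <- edges[types[edges[, 1]] == types[edges[, 2]], , drop = FALSE]
  } else same <- matrix(integer(0), 0, 2)
  g <- igraph::make_graph(edges = as.vector(t(same)), n = n,
                          directed = FALSE)
  comp <- igraph::components(g)
  memb <- unname(split(seq_len(n), comp$membership))
  out <- list(I = list(), II = list())
  for (m in memb) {
    if (length(m) >= min_size) {
      ty <- types[m[1]]
      out[[ty]] <- c(out[[ty]], list(m))
    }
  }
  out
}

#' Classify a fiber population into a myopathological diagnosis
#'
#' Rule cascade (first match wins):
#' \enumerate{
#'   \item chronic neurogenic atrophy: at least one type I and one type II
#'     contiguous fiber group of `group_min_size` or more fibers each;
#'   \item type II fiber atrophy: more than half of the type II fibers have
#'     a minimal Feret diameter more than 12\% below the mean minimal Feret
#'     diameter of the type I fibers;
#'   \item unspecific myositic changes: any endomysial or perimysial
#'     inflammatory infiltrate flag (the specific myositides are not
#'     modeled);
#'   \item unspecific myopathological changes: any minor finding (atrophic
#'     fibers, nuclear clumps, ragged-red or COX-negative fibers, more than
#'     3\% fibers with centralized nuclei);
#'   \item otherwise normal.
#' }
#' The atrophy reference is the population mean of the type I minimal Feret
#' diameters; with no type I fibers that rule is inapplicable and skipped
#' with a warning.
#'
#' @param population a `fiber_population`.
#' @param group_min_size group-size threshold for rule 1.
#' @return one diagnosis label (character).
#' @export
classify_biopsy <- function(population, group_min_size = 15L) {
  stopifnot(length(population$types) > 0)
  grp <- detect_fiber_type_groups(population, min_size = group_min_size)
  if (length(grp$I) >= 1 && length(grp$II) >= 1)
    return("chronic_neurogenic_atrophy")
  d <- population$min_feret_um
  is1 <- population$types == "I"; is2 <- population$types == "II"
  if (!any(is1)) {
    warning("no type I fibers: type II atrophy rule inapplicable")
  } else if (any(is2)) {
    ref <- mean(d[is1])
    if (mean(d[is2] < 0.88 * ref) > 0.5) return("type2_fiber_atrophy")
  }
  if (isTRUE(population$infiltrate_endomysial) ||
      isTRUE(population$infiltrate_perimysial))
    return("unspecific_myositic")
  minor <- function(x) !is.null(x) && !is.na(x) && x > 0
  if (minor(population$n_atrophic_fibers) ||
      minor(population$n_nuclear_clumps) ||
      minor(population$n_ragged_red) ||
      minor(population$n_cox_negative) ||
      (!is.null(population$frac_centralized_nuclei) &&
       population$frac_centralized_nuclei > 0.03))
    return("unspecific_myopathological")
  "normal"
}
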