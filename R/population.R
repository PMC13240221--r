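# Synthetic fiber populations with planted myopathological phenotypes, used
# to exercise the diagnostic rules without images. Fibers live on a
# triangular (hexagonal-neighborhood) lattice whose edges stand for shared
# endomysial boundaries.

# triangular-lattice adjacency for n fibers arranged in offset rows
hex_lattice_edges <- function(n) {
  k <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1L) %/% k
  col <- (seq_len(n) - 1L) %% k
  at <- function(r, c) {
    i <- r * k + c + 1L
    if (r < 0 || c < 0 || c >= k || i > n) NA_integer_ else i
  }
  edges <- matrix(integer(0), 0, 2)
  buf <- vector("list", n)
  for (i in seq_len(n)) {
    r <- row[i]; c <- col[i]
    d <- if (r %% 2 == 0) 1L else -1L  # offset-row diagonal direction
    nbr <- c(at(r, c + 1L), at(r + 1L, c), at(r + 1L, c + d))
    nbr <- nbr[!is.na(nbr)]
    if (length(nbr)) buf[[i]] <- cbind(i, nbr)
  }
  e <- do.call(rbind, buf)
  if (is.null(e)) e <- matrix(integer(0), 0, 2)
  colnames(e) <- c("from", "to")
  e
}

# grow a connected patch of `size` fibers by breadth-first search from a seed
grow_patch <- function(start, size, nb, avoid = integer(0)) {
  patch <- start; frontier <- start
  while (length(patch) < size && length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(nb[frontier])), c(patch, avoid))
    if (length(nxt) == 0) break
    take <- utils::head(nxt, size - length(patch))
    patch <- c(patch, take); frontier <- take
  }
  patch
}

#' Generate a fiber population with a planted pathology phenotype
#'
#' Produces fiber types, minimal Feret diameters, the adjacency graph, and
#' the ancillary finding flags that the diagnostic rules consume.
#' Phenotypes:
#' \describe{
#'   \item{normal}{types assigned independently (optionally spatially
#'     clustered); both types share the same diameter distribution.}
#'   \item{neurogenic_grouping}{plants at least one contiguous type I and
#'     one contiguous type II group of `group_size` fibers or more, the
#'     grouping pattern of reinnervation, plus sporadic atrophic fibers and
#'     nuclear clumps.}
#'   \item{type2_atrophy}{type II diameters are drawn from a distribution
#'     shifted low enough that more than `atrophic_fraction` of them fall
#'     below 88\% of the mean type I diameter.}
#' }
#'
#' @param n_fibers number of fibers (at least 30).
#' @param phenotype one of `"normal"`, `"neurogenic_grouping"`,
#'   `"type2_atrophy"`.
#' @param params list overriding defaults: `group_size` (15),
#'   `atrophic_fraction` (0.9), `type2_fraction` (0.3), `type_clustering`
#'   (0), `mean_type1_feret_um` (60), `feret_cv` (0.15).
#' @param seed integer seed.
#' @return object of class `fiber_population`: `types`, `min_feret_um`,
#'   `adjacency`, finding counts/flags (`n_atrophic_fibers`,
#'   `n_nuclear_clumps`, `n_ragged_red`, `n_cox_negative`,
#'   `frac_centralized_nuclei`, `infiltrate_endomysial`,
#'   `infiltrate_perimysial`).
#' @export
generate_pathological_population <- function(n_fibers,
                                             phenotype = c("normal",
                                                           "neurogenic_grouping",
                                                           "type2_atrophy"),
                                             params = list(), seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (n_fibers < 30) stop("n_fibers must be at least 30")
  p <- utils::modifyList(list(group_size = 15L, atrophic_fraction = 0.9,
                              type2_fraction = 0.3, type_clustering = 0,
                              mean_type1_feret_um = 60, feret_cv = 0.15),
                         params)
  edges <- hex_lattice_edges(n_fibers)
  nb <- vector("list", n_fibers)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  sdlog <- sqrt(log(1 + p$feret_cv^2))
  mlog1 <- log(p$mean_type1_feret_um) - sdlog^2 / 2
  withr::with_seed(seed, {
    types <- ifelse(stats::runif(n_fibers) < p$type2_fraction, "II", "I")
    n_atrophic <- 0L; n_clumps <- 0L
    if (phenotype == "normal") {
      types <- potts_cluster_types(types, edges, p$type_clustering)
    } else if (phenotype == "neurogenic_grouping") {
      # plant one contiguous group of each type (a little above the
      # threshold so that lattice edge effects cannot shrink it below)
      size <- p$group_size + 2L
      s2 <- sample.int(n_fibers, 1)
      patch2 <- grow_patch(s2, size, nb)
      rest <- setdiff(seq_len(n_fibers), patch2)
      s1 <- rest[which.max(abs(rest - s2))]
      patch1 <- grow_patch(s1, size, nb, avoid = patch2)
      types[patch2] <- "II"; types[patch1] <- "I"
      n_atrophic <- max(1L, round(0.05 * n_fibers))
      n_clumps <- 2L
    }
    d <- numeric(n_fibers)
    is1 <- types == "I"; is2 <- !is1
    d[is1] <- stats::rlnorm(sum(is1), mlog1, sdlog)
    if (phenotype == "type2_atrophy" && any(is2)) {
      # shift chosen so the expected fraction of type II diameters below
      # 0.88 * mean(type I) exceeds atrophic_fraction with margin
      z <- stats::qnorm(min(p$atrophic_fraction + 0.05, 0.995))
      f <- 0.88 * exp(sdlog^2 / 2 - sdlog * z)
      d[is2] <- stats::rlnorm(sum(is2),
                              log(f * p$mean_type1_feret_um) - sdlog^2 / 2,
                              sdlog)
    } else {
      d[is2] <- stats::rlnorm(sum(is2), mlog1, sdlog)
    }
    structure(list(types = types, min_feret_um = d, adjacency = edges,
                   n_atrophic_fibers = n_atrophic,
                   n_nuclear_clumps = n_clumps,
                   n_ragged_red = 0L, n_cox_negative = 0L,
                   frac_centralized_nuclei = 0,
                   infiltrate_endomysial = FALSE,
                   infiltrate_perimysial = FALSE,
                   phenotype = phenotype),
              class = "fiber_population")
  })
}
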