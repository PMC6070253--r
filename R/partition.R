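#' Canonicalize a species partition
#'
#' A partition assigns each species to one of `sigma` functional groups. It
#' is represented as an integer vector of group labels, named by species.
#' The canonical form renumbers groups by order of first occurrence along
#' the species vector, so two labellings of the same grouping compare equal
#' with `identical()`.
#'
#' @param partition Integer (or factor/character) vector of group labels,
#'   one per species, optionally named.
#' @return A named integer vector with labels in `1:sigma`, groups numbered
#'   by the smallest species index they contain. Canonicalization is
#'   idempotent and label-permutation invariant.
#' @export
#' @examples
#' canonicalize_partition(c(X = 2, Y = 1, Z = 1))
canonicalize_partition <- function(partition) {
  if (length(partition) == 0) abort("Empty partition.")
  if (anyNA(partition)) abort("Every species must be assigned to a group.")
  g <- match(as.vector(partition), unique(as.vector(partition)))
  names(g) <- names(partition)
  g
}

#' Number of groups of a partition
#' @param partition A species partition (see [canonicalize_partition()]).
#' @return Integer: the number of distinct groups.
#' @export
n_groups <- function(partition) length(unique(as.vector(partition)))

#' Split a partition into a list of species-index groups
#' @inheritParams n_groups
#' @return A list of integer vectors of species indices, one per group,
#'   ordered by canonical group label.
#' @export
partition_groups <- function(partition) {
  g <- canonicalize_partition(partition)
  unname(split(seq_along(g), g))
}

#' Pair-counting Jaccard index between two species partitions
#'
#' Measures agreement between an estimated and a reference clustering of the
#' same species: the number of species pairs placed in the same group by
#' both partitions, divided by the number of pairs placed together by at
#' least one. It is 1 exactly when the two partitions are identical up to
#' group labels. When both partitions are all-singletons the ratio is 0/0;
#' it is defined as 1 (the two partitions agree).
#'
#' @param p1,p2 Species partitions over the same species set, in the same
#'   species order (names, if present on both, must match).
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' jaccard_partitions(c(1, 1, 2), c(2, 2, 1)) # identical up to labels -> 1
#' jaccard_partitions(c(1, 1, 2), c(1, 2, 2)) # -> 0
jaccard_partitions <- function(p1, p2) {
  if (length(p1) != length(p2)) abort("Partitions cover different species sets.")
  if (!is.null(names(p1)) && !is.null(names(p2)) && !identical(names(p1), names(p2))) {
    abort("Partitions are over different (or differently ordered) species.")
  }
  g1 <- as.vector(p1)
  g2 <- as.vector(p2)
  co1 <- outer(g1, g1, "==")
  co2 <- outer(g2, g2, "==")
  ut <- upper.tri(co1)
  inter <- sum(co1[ut] & co2[ut])
  union <- sum(co1[ut] | co2[ut])
  if (union == 0) return(1)
  inter / union
}

#' Reference partition with the two largest groups merged
#'
#' In sparse sampling designs the species of the largest functional groups
#' are the hardest to tell apart. A coarser reference that merges the two
#' largest true groups (size ties broken towards the lowest canonical group
#' labels) scores whether the small, well-identified groups were recovered.
#'
#' @param partition A species partition with at least 3 groups.
#' @return A canonical partition with one group fewer.
#' @export
#' @examples
#' p <- rep(1:4, c(1, 2, 6, 7))
#' table(merge_largest_groups(p)) # sizes 1, 2, 13
merge_largest_groups <- function(partition) {
  g <- canonicalize_partition(partition)
  sizes <- tabulate(g)
  if (length(sizes) < 3) abort("Need at least 3 groups to merge the two largest.")
  ord <- order(-sizes, seq_along(sizes)) # by size desc, ties -> lowest label
  keep <- ord[1:2]
  g[g == keep[2]] <- keep[1]
  canonicalize_partition(g)
}
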