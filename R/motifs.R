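# Internal vectorized engine -------------------------------------------------
#
# All fitting operations reduce to cross-tabulations of the presence matrix
# P (n x s, double 0/1) by the motif index k (length n, values 1..m in order
# of first appearance). They are kept free of per-ecosystem loops: the tree
# search evaluates hundreds of candidate partitions per build.

# motif index (1..m, by first appearance) of each ecosystem under grouping g
motif_index_of <- function(P, g) {
  sigma <- max(g)
  Gind <- matrix(0, length(g), sigma)
  Gind[cbind(seq_along(g), g)] <- 1
  G <- (P %*% Gind) > 0 # n x sigma: group j represented in ecosystem?
  code <- as.vector(G %*% 2^(seq_len(sigma) - 1))
  match(code, unique(code))
}

# motif key strings ("1+3") for reporting, aligned with motif_index_of()
motif_key_of <- function(P, g) {
  sigma <- max(g)
  Gind <- matrix(0, length(g), sigma)
  Gind[cbind(seq_along(g), g)] <- 1
  G <- (P %*% Gind) > 0
  apply(G, 1, function(r) paste(which(r), collapse = "+"))
}

# modelled function: for each ecosystem, the unweighted mean over its own
# species i of the mean observed function of ecosystems that share its motif
# and contain i.
modelled_values <- function(P, F, k) {
  S <- rowsum(P * F, k, reorder = FALSE) # m x s sums of F over A_{i,k}
  C <- rowsum(P, k, reorder = FALSE) # m x s sizes of A_{i,k}
  Mm <- S / C
  Mm[C == 0] <- 0 # never selected (P[A,i]=1 implies C[k,i]>=1)
  rowSums(P * Mm[k, , drop = FALSE]) / rowSums(P)
}

# leave-one-out predictions: the modelled value recomputed with the focal
# ecosystem removed from every cluster. Species terms whose depleted cluster
# is empty are dropped; the prediction is NA when the ecosystem is the sole
# representative of its motif, or when no species term survives.
loo_values <- function(P, F, k) {
  S <- rowsum(P * F, k, reorder = FALSE)
  C <- rowsum(P, k, reorder = FALSE)
  Sd <- S[k, , drop = FALSE] - P * F # depleted sums
  Cd <- C[k, , drop = FALSE] - P # depleted counts
  W <- P * (Cd > 0) # surviving species terms
  vals <- Sd / Cd
  vals[Cd == 0] <- 0
  nterm <- rowSums(W)
  pred <- rowSums(W * vals)
  pred <- ifelse(nterm > 0, pred / nterm, NA_real_)
  pred[tabulate(k)[k] == 1] <- NA_real_
  pred
}

r2_of_grouping <- function(P, F, g, tss) {
  k <- motif_index_of(P, g)
  1 - sum((F - modelled_values(P, F, k))^2) / tss
}

total_ss <- function(F) sum((F - mean(F))^2)

check_partition_for <- function(sample, partition) {
  if (length(partition) != n_species(sample)) {
    abort("`partition` must assign each species of the sample to a group.")
  }
  if (!is.null(names(partition)) &&
    !identical(names(partition), sample$species)) {
    abort("`partition` names do not match the sample's species.")
  }
  canonicalize_partition(partition)
}

# Public surface --------------------------------------------------------------

#' Assign an assembly motif to each ecosystem
#'
#' An assembly motif is the combination of functional groups represented in
#' an ecosystem: under a partition of the species into `sigma` groups, the
#' motif of an ecosystem is the set of groups to which its species belong.
#' Ecosystems sharing a motif form a motif cluster; the model treats them as
#' functionally alike.
#'
#' @param sample An [eco_sample()].
#' @param partition A species partition (length `n_species(sample)`).
#' @return An object of class `motif_classification`: a list with
#'   `motif_index` (integer, 1..m by first appearance), `motif_key`
#'   (character, group labels joined by `+`), `m` (number of observed
#'   motifs), `clusters` (named list of ecosystem index vectors), and the
#'   canonical `partition`. `m` never exceeds `min(n, 2^sigma - 1)`.
#' @export
#' @seealso [modelled_function()], [loo_predictions()], [motif_fit()]
assign_motifs <- function(sample, partition) {
  stopifnot(inherits(sample, "eco_sample"))
  g <- check_partition_for(sample, partition)
  k <- motif_index_of(sample$presence, g)
  key <- motif_key_of(sample$presence, g)
  structure(
    list(
      motif_index = k,
      motif_key = key,
      m = max(k),
      clusters = split(seq_along(k), factor(key, levels = unique(key))),
      partition = stats::setNames(g, sample$species)
    ),
    class = "motif_classification"
  )
}

#' @export
print.motif_classification <- function(x, ...) {
  cat(sprintf(
    "<motif_classification> %d ecosystems in %d motifs (sigma = %d)\n",
    length(x$motif_index), x$m, n_groups(x$partition)
  ))
  invisible(x)
}

#' @export
as_tibble.motif_classification <- function(x, ...) {
  tibble::tibble(
    ecosystem = seq_along(x$motif_index),
    motif = x$motif_key,
    motif_index = x$motif_index
  )
}

#' Ecosystems of a motif cluster that contain a given species
#'
#' The species-motif cluster of species `i` and motif `k` is the set of
#' ecosystems that share motif `k` and contain at least one individual of
#' species `i`; its mean observed function is the building block of the
#' modelled function.
#'
#' @inheritParams assign_motifs
#' @param classification An [assign_motifs()] result for `sample`.
#' @param species Species name or index.
#' @param motif Motif key (as in `classification$motif_key`).
#' @return Integer vector of ecosystem row indices (possibly empty).
#' @export
species_motif_cluster <- function(sample, classification, species, motif) {
  if (is.character(species)) species <- match(species, sample$species)
  members <- classification$clusters[[motif]]
  if (is.null(members)) return(integer(0))
  members[sample$presence[members, species] == 1]
}

#' Modelled ecosystem function under a motif classification
#'
#' The modelled function of an ecosystem is the unweighted average, over the
#' species it contains, of the mean observed function of the ecosystems
#' that share its assembly motif and contain that species. Every entry is
#' defined, since an ecosystem always belongs to the cluster of each of its
#' own species.
#'
#' @inheritParams species_motif_cluster
#' @return Numeric vector of length `n_ecosystems(sample)`.
#' @export
modelled_function <- function(sample, classification) {
  stopifnot(inherits(classification, "motif_classification"))
  modelled_values(
    sample$presence, sample$function_values,
    classification$motif_index
  )
}

#' Leave-one-out predicted ecosystem function
#'
#' Recomputes the modelled function of each ecosystem with that ecosystem
#' removed from every species-motif cluster, keeping the species partition
#' fixed. Species terms whose depleted cluster is empty are dropped from the
#' average. The prediction is undefined (`NA`) when the ecosystem is the
#' sole representative of its motif (no independent information exists), or
#' in the rarer case that no species term survives depletion.
#'
#' @inheritParams species_motif_cluster
#' @return A list with `predicted` (numeric, `NA` where undefined),
#'   `defined` (logical) and `predicting_ratio` (fraction of ecosystems with
#'   a defined prediction).
#' @export
loo_predictions <- function(sample, classification) {
  stopifnot(inherits(classification, "motif_classification"))
  pred <- loo_values(
    sample$presence, sample$function_values,
    classification$motif_index
  )
  list(
    predicted = pred,
    defined = !is.na(pred),
    predicting_ratio = mean(!is.na(pred))
  )
}
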