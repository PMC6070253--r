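TREE_SCHEMA_VERSION <- 1L

#' Serialize / restore a clustering tree
#'
#' The JSON artifact stores the full tree: per-level partitions and
#' statistics, per-ecosystem modelled and predicted values, configuration
#' and provenance (seed, sample hash, timestamp), under an explicit schema
#' version.
#'
#' @param tree A [build_tree()] result.
#' @param path File path.
#' @return `write_tree_json()` returns `path` invisibly; `read_tree_json()`
#'   returns a `motif_tree`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "motif_tree"))
  payload <- list(
    schema_version = TREE_SCHEMA_VERSION,
    species = tree$species,
    ecosystem_ids = tree$ecosystem_ids,
    function_values = tree$function_values,
    partitions = lapply(tree$partitions, unname),
    level_stats = tree$level_stats,
    tree_stats = tree$tree_stats,
    modelled = tree$modelled,
    predicted = tree$predicted,
    sigma_prime_levels = tree$sigma_prime_levels,
    split_parent = tree$split_parent,
    split_nucleus = tree$split_nucleus,
    evaluation_count = tree$evaluation_count,
    tss = tree$tss,
    n = tree$n,
    s = tree$s,
    sigma_max = tree$sigma_max,
    sigma_opt = tree$sigma_opt,
    config = tree$config,
    provenance = tree$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || x$schema_version != TREE_SCHEMA_VERSION) {
    abort(sprintf(
      "Unsupported tree schema version: %s.", format(x$schema_version)
    ))
  }
  parts <- x$partitions
  if (is.matrix(parts)) parts <- asplit(parts, 1) # jsonlite simplifies to a matrix
  tree <- list(
    partitions = lapply(parts, function(g) {
      stats::setNames(as.integer(g), x$species)
    }),
    level_stats = tibble::as_tibble(x$level_stats),
    tree_stats = tibble::as_tibble(x$tree_stats),
    modelled = as.matrix(x$modelled),
    predicted = as.matrix(x$predicted),
    sigma_prime_levels = as.matrix(x$sigma_prime_levels),
    split_parent = as.integer(x$split_parent),
    split_nucleus = as.integer(x$split_nucleus),
    evaluation_count = as.integer(x$evaluation_count),
    tss = x$tss,
    n = as.integer(x$n),
    s = as.integer(x$s),
    species = x$species,
    ecosystem_ids = x$ecosystem_ids,
    function_values = as.numeric(x$function_values),
    config = x$config,
    provenance = x$provenance,
    sigma_max = as.integer(x$sigma_max),
    sigma_opt = as.integer(x$sigma_opt)
  )
  tree$defined <- !is.na(tree$predicted)
  dimnames(tree$modelled) <- dimnames(tree$predicted) <- NULL
  dimnames(tree$sigma_prime_levels) <- NULL
  class(tree) <- "motif_tree"
  tree
}

#' Export the species-clustering dendrogram in Newick format
#'
#' The divisive tree is a binary dendrogram over the species: each internal
#' node is one group split, labelled by the level (number of groups) at
#' which the split happens; all branch lengths are 1. The output is readable
#' by standard phylogenetic tools (e.g. `ape::read.tree()`).
#'
#' @inheritParams write_tree_json
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "motif_tree"))
  newick_of <- function(members) {
    if (length(members) == 1) {
      return(tree$species[members])
    }
    # first level at which this species set is assigned >1 group
    for (sigma in 2:tree$s) {
      labs <- tree$partitions[[sigma]][members]
      if (length(unique(labs)) > 1) {
        parts <- split(members, labs)
        stopifnot(length(parts) == 2) # one split per level
        return(sprintf(
          "(%s:1,%s:1)%d",
          newick_of(parts[[1]]), newick_of(parts[[2]]), sigma
        ))
      }
    }
  }
  writeLines(paste0(newick_of(seq_len(tree$s)), ";"), path)
  invisible(path)
}

#' Export per-level tree statistics as CSV
#'
#' One row per level: `sigma`, `m`, model-level and tree-level fit
#' statistics, AICc.
#'
#' @inheritParams write_tree_json
#' @return `path`, invisibly.
#' @export
write_level_stats <- function(tree, path) {
  stopifnot(inherits(tree, "motif_tree"))
  readr::write_csv(tidy(tree), path, progress = FALSE)
  invisible(path)
}

#' Read / write a species partition as CSV
#'
#' Two columns: `species`, `group`.
#'
#' @param partition A named species partition.
#' @param path File path.
#' @return `read_partition()` returns a named canonical partition.
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(
    tibble::tibble(
      species = names(partition) %||% paste0("sp", seq_along(partition)),
      group = as.integer(canonicalize_partition(partition))
    ),
    path,
    progress = FALSE
  )
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species", "group") %in% names(df))) {
    abort("Partition file must have columns `species` and `group`.")
  }
  canonicalize_partition(stats::setNames(df$group, df$species))
}
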