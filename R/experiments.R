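# Study designs emulated by the replicated experiments ------------------------
#
# microbial: 6 species, every combination assembled (63 microcosms including
#   monocultures), motif means uniform on 0.4-1.4 function units, relative
#   error 0.08, base structure 1/2/3.
# grassland: 16 species, pluri-species combinations only (65519 possible),
#   sampled without replacement, motif means uniform on 50-550 g m^-2,
#   relative error 0.17, base structure 1/2/6/7.
experiment_designs <- list(
  microbial = list(
    base_sizes = c(1L, 2L, 3L), mean_interval = c(0.4, 1.4), cv = 0.08,
    design = "full_factorial", include_monocultures = TRUE, sample_size = NULL
  ),
  grassland = list(
    base_sizes = c(1L, 2L, 6L, 7L), mean_interval = c(50, 550), cv = 0.17,
    design = "sample", include_monocultures = FALSE, sample_size = 2048L
  )
)

#' Nested true structures around a base functional structure
#'
#' The replicated experiments vary the true number of functional groups
#' while keeping the same species pool. Structures are derived from a base
#' group-size vector by a deterministic rule: to add a group, the largest
#' group (ties towards the first) is split into two near-halves; to remove
#' one, the two largest groups are merged. This mirrors how structures
#' refine from the trunk to the leaves of a clustering tree.
#'
#' @param base_sizes Integer vector of base group sizes.
#' @param sigma Desired number of groups (1 to `sum(base_sizes)`).
#' @return An integer vector of `sigma` group sizes summing to
#'   `sum(base_sizes)`.
#' @export
#' @examples
#' nested_structure(c(1, 2, 3), 2) # 1, 5
#' nested_structure(c(1, 2, 6, 7), 3) # 1, 2, 13
nested_structure <- function(base_sizes, sigma) {
  sizes <- as.integer(base_sizes)
  s <- sum(sizes)
  if (sigma < 1 || sigma > s) abort("`sigma` must be between 1 and the species count.")
  while (length(sizes) > sigma) {
    ord <- order(-sizes, seq_along(sizes))
    i <- sort(ord[1:2])
    sizes[i[1]] <- sizes[i[1]] + sizes[i[2]]
    sizes <- sizes[-i[2]]
  }
  while (length(sizes) < sigma) {
    i <- which.max(sizes)
    q <- sizes[i]
    if (q < 2) abort("No group left to split.")
    sizes <- append(sizes[-i], c(ceiling(q / 2), floor(q / 2)), after = i - 1)
  }
  sizes
}

# per-replicate seeds: one upfront draw from the base seed, in replicate order
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2^31 - 1, n)
}

# generate one virtual dataset, analyse it, score recovery
analyse_replicate <- function(group_sizes, mean_interval, cv, design,
                              sample_size, include_monocultures, seed) {
  cfg <- simulation_config(
    group_sizes = group_sizes, mean_interval = mean_interval, cv = cv,
    design = design, sample_size = sample_size,
    include_monocultures = include_monocultures, seed = seed
  )
  vd <- generate_dataset(cfg)
  tree <- build_tree(vd$sample, seed = seed)
  truth <- vd$true_partition
  sigma_true <- n_groups(truth)
  opt <- tree$sigma_opt
  jac_opt <- jaccard_partitions(tree$partitions[[opt]], truth)
  jac_true <- jaccard_partitions(tree$partitions[[sigma_true]], truth)
  jac_merged <- NA_real_
  if (sigma_true >= 3) {
    ref <- merge_largest_groups(truth)
    jac_merged <- jaccard_partitions(tree$partitions[[n_groups(ref)]], ref)
  }
  ts <- tree$tree_stats
  tibble::tibble(
    seed = seed,
    sigma_true = sigma_true,
    sigma_opt = opt,
    sigma_max = tree$sigma_max,
    jaccard_opt = jac_opt,
    jaccard_true = jac_true,
    jaccard_merged = jac_merged,
    r2_tree = ts$r2_tree[opt],
    e_tree = ts$e_tree[opt],
    ratio = ts$e_tree[opt] / ts$r2_tree[opt]
  )
}

run_replicates <- function(spec_tbl, seed) {
  seeds <- derive_seeds(seed, nrow(spec_tbl))
  purrr::map_dfr(seq_len(nrow(spec_tbl)), function(i) {
    row <- spec_tbl[i, ]
    res <- analyse_replicate(
      group_sizes = row$group_sizes[[1]],
      mean_interval = row$mean_interval[[1]],
      cv = row$cv,
      design = row$design,
      sample_size = if (is.na(row$sample_size)) NULL else row$sample_size,
      include_monocultures = row$include_monocultures,
      seed = seeds[i]
    )
    dplyr::bind_cols(tibble::tibble(replicate = row$replicate), res)
  })
}

#' Structure-recovery accuracy across true numbers of functional groups
#'
#' Replicates the accuracy experiment: virtual datasets are generated for a
#' range of true structures (nested around the design's base structure),
#' each is analysed by [build_tree()], and the recovered partition is scored
#' against the truth by the pair-counting Jaccard index, both at the
#' AICc-selected level (`jaccard_opt`) and at the level with the true number
#' of groups (`jaccard_true`).
#'
#' @param design `"microbial"` (6 species, all 63 combinations, cv 0.08) or
#'   `"grassland"` (16 species, sampled pluri-species combinations, cv
#'   0.17).
#' @param sigma_true Integer vector of true group numbers to simulate.
#' @param n_reps Replicate datasets per `sigma_true`.
#' @param seed Base seed; per-replicate seeds are drawn from it upfront, so
#'   results are reproducible bit-for-bit.
#' @param sample_size Ecosystems sampled per dataset (grassland design).
#' @param cv Override of the design's relative error.
#' @return A tibble with one row per replicate: seeds, true and selected
#'   numbers of groups, Jaccard scores, tree statistics at the selected
#'   level, and the ratio `e_tree / r2_tree`.
#' @export
run_accuracy_experiment <- function(design = c("microbial", "grassland"),
                                    sigma_true = NULL,
                                    n_reps = 100,
                                    seed = 1,
                                    sample_size = NULL,
                                    cv = NULL) {
  design <- match.arg(design)
  d <- experiment_designs[[design]]
  s <- sum(d$base_sizes)
  sigma_true <- sigma_true %||% if (design == "microbial") 2:5 else 2:9
  spec_tbl <- tidyr::expand_grid(
    sigma_true_ = sigma_true,
    replicate = seq_len(n_reps)
  )
  spec_tbl <- dplyr::mutate(
    spec_tbl,
    group_sizes = purrr::map(.data$sigma_true_, ~ nested_structure(d$base_sizes, .x)),
    mean_interval = list(d$mean_interval),
    cv = cv %||% d$cv,
    design = d$design,
    sample_size = (sample_size %||% d$sample_size) %||% NA_integer_,
    include_monocultures = d$include_monocultures
  )
  out <- run_replicates(spec_tbl, seed)
  dplyr::relocate(out, dplyr::all_of(c("sigma_true", "replicate")))
}

#' Sensitivity of structure recovery to the relative error
#'
#' Replicates the error-sensitivity experiment: the 6-species pool with true
#' groups of sizes 1, 2 and 3, every combination observed, and the relative
#' error varied along a doubling grid.
#'
#' @param cv_grid Relative-error levels (default doubling 0.02 to 1.28).
#' @inheritParams run_accuracy_experiment
#' @return A tibble, one row per replicate, with a `cv` column.
#' @export
run_error_sensitivity_experiment <- function(cv_grid = 0.02 * 2^(0:6),
                                             n_reps = 100,
                                             seed = 1) {
  d <- experiment_designs$microbial
  spec_tbl <- tidyr::expand_grid(cv = cv_grid, replicate = seq_len(n_reps))
  spec_tbl <- dplyr::mutate(
    spec_tbl,
    group_sizes = list(d$base_sizes),
    mean_interval = list(d$mean_interval),
    design = d$design,
    sample_size = NA_integer_,
    include_monocultures = d$include_monocultures
  )
  out <- run_replicates(spec_tbl, seed)
  dplyr::bind_cols(spec_tbl["cv"], out) |>
    dplyr::relocate(dplyr::all_of(c("cv", "replicate")))
}

#' Effect of sampling effort on structure recovery
#'
#' Replicates the sampling-effort experiment: the 16-species pool with true
#' groups of sizes 1, 2, 6 and 7, relative error 0.17, and the number of
#' sampled pluri-species ecosystems varied along a doubling grid. Besides
#' the 4-group truth, recovery is also scored against the 3-group reference
#' obtained by merging the two largest true groups (`jaccard_merged`).
#'
#' @param sizes Sampling-effort grid (default doubling 32 to 2048).
#' @inheritParams run_accuracy_experiment
#' @return A tibble, one row per replicate, with a `sample_size` column.
#' @export
run_sampling_effort_experiment <- function(sizes = 2^(5:11),
                                           n_reps = 100,
                                           seed = 1,
                                           cv = NULL) {
  d <- experiment_designs$grassland
  spec_tbl <- tidyr::expand_grid(sample_size = as.integer(sizes), replicate = seq_len(n_reps))
  spec_tbl <- dplyr::mutate(
    spec_tbl,
    group_sizes = list(d$base_sizes),
    mean_interval = list(d$mean_interval),
    cv = cv %||% d$cv,
    design = d$design,
    include_monocultures = d$include_monocultures
  )
  out <- run_replicates(spec_tbl, seed)
  dplyr::bind_cols(spec_tbl["sample_size"], out) |>
    dplyr::relocate(dplyr::all_of(c("sample_size", "replicate")))
}

#' Summarize replicated recovery results
#'
#' @param results A tibble from one of the `run_*_experiment()` functions.
#' @param by Grouping column (e.g. `"sigma_true"`, `"cv"`,
#'   `"sample_size"`).
#' @return A tibble of per-group summaries: failure fraction (Jaccard at the
#'   AICc-selected level below 1), median Jaccard scores, mean selected
#'   sigma, mean tree statistics.
#' @export
summarize_recovery <- function(results, by) {
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      failure_rate_opt = mean(.data$jaccard_opt < 1),
      failure_rate_true = mean(.data$jaccard_true < 1),
      median_jaccard_opt = median(.data$jaccard_opt),
      median_jaccard_true = median(.data$jaccard_true),
      median_jaccard_merged = median(.data$jaccard_merged),
      mean_sigma_opt = mean(.data$sigma_opt),
      mean_r2_tree = mean(.data$r2_tree),
      mean_e_tree = mean(.data$e_tree),
      mean_ratio = mean(.data$ratio),
      .groups = "drop"
    )
}
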