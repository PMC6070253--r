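#' Deepest predictable level of each ecosystem
#'
#' Along the divisive tree, an ecosystem stays predictable until it becomes
#' the sole representative of its assembly motif. `sigma_prime()` returns,
#' for each ecosystem, the largest level `j <= up_to_sigma` at which its
#' leave-one-out prediction is defined. At the base of the tree (sigma = 1)
#' every ecosystem of a sample with n >= 2 is predictable, so the result is
#' always at least 1.
#'
#' @param tree A [build_tree()] result.
#' @param up_to_sigma Tree depth considered (defaults to the full tree).
#' @return An integer vector of length n.
#' @export
sigma_prime <- function(tree, up_to_sigma = tree$s) {
  stopifnot(inherits(tree, "motif_tree"))
  if (up_to_sigma < 1 || up_to_sigma > tree$s) {
    abort("`up_to_sigma` must be between 1 and the number of species.")
  }
  tree$sigma_prime_levels[, up_to_sigma]
}

#' Whole-tree fit statistics at a given depth
#'
#' Tree-level statistics evaluate every ecosystem at its own deepest
#' predictable level ([sigma_prime()]), so that trees cut at different
#' depths always refer to the same n ecosystems: the tree predicting ratio
#' is 1 by construction, and tree-level R-squared and efficiency are
#' normalized by the full-sample total sum of squares. They are bounded
#' above by their model-level counterparts.
#'
#' @inheritParams sigma_prime
#' @return A one-row tibble: `sigma`, `rss_tree_modelling`,
#'   `rss_tree_predicting`, `r2_tree`, `e_tree`, `predicting_ratio_tree`,
#'   `aicc`.
#' @export
tree_stats <- function(tree, up_to_sigma = tree$s) {
  stopifnot(inherits(tree, "motif_tree"))
  tree$tree_stats[up_to_sigma, ]
}

#' Validated depth of a clustering tree
#'
#' Model-level efficiency is expected to improve while splits isolate real
#' functional groups; the first strict decrease (or loss of definition)
#' signals an overfitted split, which is rejected together with all deeper
#' levels. The validated depth is the level just before that first decrease.
#'
#' @param x A [build_tree()] result, or a numeric vector of per-level
#'   model efficiencies (level 1 first).
#' @return An integer >= 1.
#' @export
#' @examples
#' sigma_max(c(0.2, 0.5, 0.4, 0.6)) # 2
sigma_max <- function(x) {
  e <- if (inherits(x, "motif_tree")) x$level_stats$efficiency else as.numeric(x)
  if (length(e) == 0) abort("No efficiency values.")
  if (length(e) >= 2) {
    for (j in 2:length(e)) {
      if (is.na(e[j]) || e[j] < e[j - 1]) {
        return(j - 1L)
      }
    }
  }
  length(e)
}

#' Tree AICc at a given number of functional groups
#'
#' Small-sample corrected Akaike criterion of the tree cut at `sigma`
#' groups: `n log(RSS_tree_modelling / n) + 2m + 2m(m+1)/(n - m + 1)`, where
#' `m` is the number of assembly motifs observed at that level (the model's
#' parametrization). Undefined (`NA`) when the correction denominator is
#' non-positive or when the RSS is numerically zero relative to the sample
#' TSS (the log-likelihood term diverges; such perfect fits are handled by
#' [sigma_opt()] directly, which prefers them over any finite criterion).
#'
#' @inheritParams sigma_prime
#' @param sigma Level(s) at which to evaluate the criterion.
#' @return Numeric vector, `NA` where undefined.
#' @export
aicc_tree <- function(tree, sigma = seq_len(tree$s)) {
  stopifnot(inherits(tree, "motif_tree"))
  tree$tree_stats$aicc[sigma]
}

#' AICc-optimal number of functional groups
#'
#' The optimal number of groups minimizes the tree AICc over the validated
#' levels `1..sigma_max` (or over `1..(s-1)` with `range = "full"`, matching
#' the criterion's nominal search range). Levels with an exactly zero
#' modelling RSS fit perfectly and are preferred over any finite-AICc level;
#' all ties are resolved towards the smallest number of groups (parsimony).
#'
#' @inheritParams sigma_prime
#' @param range `"validated"` (default) or `"full"`; defaults to the choice
#'   recorded when the tree was built.
#' @return An integer >= 1.
#' @export
sigma_opt <- function(tree, range = tree$config$sigma_opt_range) {
  stopifnot(inherits(tree, "motif_tree"))
  range <- match.arg(range, c("validated", "full"))
  top <- if (range == "validated") sigma_max(tree) else max(tree$s - 1L, 1L)
  aicc <- tree$tree_stats$aicc[seq_len(top)]
  rss <- tree$tree_stats$rss_tree_modelling[seq_len(top)]
  score <- aicc
  floor <- perfect_fit_floor(tree$tss %||% 0)
  score[rss <= floor] <- -Inf # perfect fit dominates any finite criterion
  if (all(is.na(score))) {
    abort("AICc is undefined at every candidate level; no selection possible.")
  }
  as.integer(which.min(score)) # which.min skips NA, ties -> smallest sigma
}
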