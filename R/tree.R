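# Greedy split of one functional group --------------------------------------
#
# Splitting a group of q species scores at most q + (q-1) + ... + 2
# = q(q+1)/2 - 1 candidate partitions: q nucleus isolations, then
# steepest-ascent single-species moves until no strictly positive gain.
split_group_engine <- function(P, F, tss, g, grp) {
  members <- which(g == grp)
  if (length(members) < 2) {
    abort(sprintf("Group %s is a singleton and cannot be split.", format(grp)))
  }
  new_label <- max(g) + 1L
  evals <- 0L

  # nucleus: the species whose isolation maximizes R^2 (ties -> lowest index)
  best_nucleus <- NA_integer_
  best_r2 <- -Inf
  for (sp in members) {
    cand <- g
    cand[sp] <- new_label
    r2 <- r2_of_grouping(P, F, cand, tss)
    evals <- evals + 1L
    if (r2 > best_r2) {
      best_r2 <- r2
      best_nucleus <- sp
    }
  }
  current <- g
  current[best_nucleus] <- new_label
  best_partition <- current

  # steepest-ascent move path: per round the single best move is made (ties
  # towards the lowest species index) and the walk continues to the end of
  # the group, so a locally flat or decreasing round cannot trap the search;
  # the clustering with the maximal R^2 seen anywhere along the path is kept.
  remaining <- setdiff(members, best_nucleus)
  current_r2 <- best_r2
  while (length(remaining) >= 2) {
    best_move <- NA_integer_
    best_move_r2 <- -Inf
    for (sp in remaining) {
      cand <- current
      cand[sp] <- new_label
      r2 <- r2_of_grouping(P, F, cand, tss)
      evals <- evals + 1L
      if (r2 > best_move_r2) {
        best_move_r2 <- r2
        best_move <- sp
      }
    }
    current[best_move] <- new_label
    current_r2 <- best_move_r2
    remaining <- setdiff(remaining, best_move)
    if (current_r2 > best_r2) {
      best_r2 <- current_r2
      best_partition <- current
    }
  }
  list(
    partition = best_partition, r_squared = best_r2,
    nucleus = best_nucleus, evaluations = evals
  )
}

#' Best split of one functional group into two
#'
#' Searches for the division of one group of a species partition that
#' maximizes the coefficient of determination of the resulting
#' (sigma+1)-model. A nucleus species is first isolated (the isolation with
#' the highest R-squared; ties broken towards the lowest species index),
#' then remaining group members are moved into the new group one at a time
#' by steepest ascent, as long as a move strictly increases R-squared.
#'
#' @inheritParams motif_fit
#' @param group Canonical label of the group to split (must contain at
#'   least two species).
#' @return A list: `partition` (canonical, sigma+1 groups), `r_squared`,
#'   `nucleus` (species index isolated first), `evaluations` (number of
#'   candidate partitions scored, at most `q(q+1)/2 - 1` for a group of `q`
#'   species).
#' @export
split_group <- function(sample, partition, group) {
  stopifnot(inherits(sample, "eco_sample"))
  g <- check_partition_for(sample, partition)
  if (!group %in% g) abort("`group` is not a label of `partition`.")
  F <- sample$function_values
  tss <- total_ss(F)
  if (tss == 0) abort("Degenerate variance: all observed function values are equal (TSS = 0).")
  res <- split_group_engine(sample$presence, F, tss, g, group)
  res$partition <- stats::setNames(
    canonicalize_partition(res$partition),
    sample$species
  )
  res
}

#' Build the hierarchical divisive tree of species clusterings
#'
#' Starting from all species in one functional group (sigma = 1), each level
#' splits exactly one group of the previous partition into two, choosing
#' over all splittable groups the split whose (sigma+1)-model maximizes the
#' coefficient of determination ([split_group()]); ties are broken towards
#' the group containing the lowest species index. The process ends with all
#' species in singletons (sigma = s), yielding one nested partition per
#' number of groups. The number of candidate partitions scored never exceeds
#' [max_evaluations()].
#'
#' Every level is fitted ([motif_fit()]), and whole-tree statistics are
#' assembled: each ecosystem is modelled and predicted at its own deepest
#' predictable level (see [sigma_prime()]), so tree-level statistics always
#' refer to all n ecosystems (tree predicting ratio 1). The validated depth
#' [sigma_max()] and the AICc-optimal number of groups [sigma_opt()] are
#' recorded.
#'
#' @inheritParams motif_fit
#' @param sigma_opt_range `"validated"` (default) restricts the AICc search
#'   to levels `1..sigma_max`; `"full"` searches `1..(s-1)`.
#' @param aicc_denominator `"n-m+1"` (default) or the textbook `"n-m-1"`
#'   small-sample correction denominator.
#' @param seed Optional integer recorded in the artifact's provenance (the
#'   build itself is deterministic).
#' @return An object of class `motif_tree`; see [tidy.motif_tree()],
#'   [glance.motif_tree()], [autoplot.motif_tree()].
#' @export
#' @examples
#' toy <- eco_sample(tibble::tibble(
#'   id = paste0("e", 1:5),
#'   X = c(1, 1, 1, 0, 1), Y = c(0, 1, 0, 1, 1), Z = c(0, 0, 1, 1, 1),
#'   f = c(10, 20, 24, 8, 22)
#' ))
#' tree <- build_tree(toy)
#' tidy(tree)
#' glance(tree)
build_tree <- function(sample, tss = c("subset", "full"),
                       sigma_opt_range = c("validated", "full"),
                       aicc_denominator = c("n-m+1", "n-m-1"),
                       seed = NA_integer_) {
  stopifnot(inherits(sample, "eco_sample"))
  tss_variant <- match.arg(tss)
  sigma_opt_range <- match.arg(sigma_opt_range)
  aicc_denominator <- match.arg(aicc_denominator)
  n <- n_ecosystems(sample)
  s <- n_species(sample)
  if (n < 2) abort("Tree building needs at least 2 ecosystems.")
  P <- sample$presence
  F <- sample$function_values
  tss_all <- total_ss(F)
  if (tss_all == 0) {
    abort("Degenerate variance: all observed function values are equal (TSS = 0).")
  }

  partitions <- vector("list", s)
  partitions[[1]] <- rep(1L, s)
  evaluation_count <- 0L
  split_parent <- rep(NA_integer_, s)
  split_nucleus <- rep(NA_integer_, s)

  if (s >= 2) {
    for (sigma in 1:(s - 1)) {
      g <- partitions[[sigma]]
      labels <- sort(unique(g))
      splittable <- labels[tabulate(g)[labels] >= 2]
      # iterate groups by their smallest species index (canonical labels are
      # already in that order); strict > keeps the lowest on ties
      best <- NULL
      best_r2 <- -Inf
      for (grp in splittable) {
        res <- split_group_engine(P, F, tss_all, g, grp)
        evaluation_count <- evaluation_count + res$evaluations
        if (res$r_squared > best_r2) {
          best_r2 <- res$r_squared
          best <- res
          best$parent <- grp
        }
      }
      partitions[[sigma + 1]] <- canonicalize_partition(best$partition)
      split_parent[sigma + 1] <- best$parent
      split_nucleus[sigma + 1] <- best$nucleus
    }
  }
  partitions <- lapply(partitions, function(g) stats::setNames(g, sample$species))

  # per-level fits
  modelled <- matrix(NA_real_, n, s)
  predicted <- matrix(NA_real_, n, s)
  stats_rows <- vector("list", s)
  for (sigma in 1:s) {
    k <- motif_index_of(P, partitions[[sigma]])
    mod <- modelled_values(P, F, k)
    pred <- loo_values(P, F, k)
    if (sigma == 1 && anyNA(pred)) {
      # with a single universal motif every ecosystem has peers; where no
      # species term survives depletion, fall back to the leave-one-out
      # grand mean so the base of the tree always predicts (n >= 2)
      idx <- which(is.na(pred))
      pred[idx] <- (sum(F) - F[idx]) / (n - 1)
    }
    eff <- efficiency_of(F, pred, tss_all, tss_variant)
    modelled[, sigma] <- mod
    predicted[, sigma] <- pred
    stats_rows[[sigma]] <- tibble::tibble(
      sigma = sigma,
      m = max(k),
      rss_modelling = sum((F - mod)^2),
      r_squared = 1 - sum((F - mod)^2) / tss_all,
      rss_predicting = eff$rss_predicting,
      efficiency = eff$efficiency,
      predicting_ratio = mean(!is.na(pred))
    )
  }
  level_stats <- dplyr::bind_rows(stats_rows)

  # deepest predictable level per ecosystem, cumulatively in sigma
  defined <- !is.na(predicted)
  sp_mat <- matrix(1L, n, s) # defined[, 1] is all TRUE by construction
  if (s >= 2) {
    for (sigma in 2:s) {
      sp_mat[, sigma] <- ifelse(defined[, sigma], sigma, sp_mat[, sigma - 1])
    }
  }
  rows <- seq_len(n)
  rss_tree_mod <- rss_tree_pred <- numeric(s)
  for (sigma in 1:s) {
    idx <- cbind(rows, sp_mat[, sigma])
    rss_tree_mod[sigma] <- sum((F - modelled[idx])^2)
    rss_tree_pred[sigma] <- sum((F - predicted[idx])^2)
  }
  m_vec <- level_stats$m
  aicc <- aicc_value(n, m_vec, rss_tree_mod, aicc_denominator,
    rss_floor = perfect_fit_floor(tss_all)
  )

  tree_stats <- tibble::tibble(
    sigma = 1:s,
    rss_tree_modelling = rss_tree_mod,
    rss_tree_predicting = rss_tree_pred,
    r2_tree = 1 - rss_tree_mod / tss_all,
    e_tree = 1 - rss_tree_pred / tss_all,
    predicting_ratio_tree = 1,
    aicc = aicc
  )

  tree <- structure(
    list(
      partitions = partitions,
      level_stats = level_stats,
      tree_stats = tree_stats,
      modelled = modelled,
      predicted = predicted,
      defined = defined,
      sigma_prime_levels = sp_mat,
      split_parent = split_parent,
      split_nucleus = split_nucleus,
      evaluation_count = evaluation_count,
      tss = tss_all,
      n = n,
      s = s,
      species = sample$species,
      ecosystem_ids = sample$ecosystem_ids,
      function_values = F,
      config = list(
        tss_variant = tss_variant,
        sigma_opt_range = sigma_opt_range,
        aicc_denominator = aicc_denominator
      ),
      provenance = list(
        seed = seed,
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        sample_hash = rlang::hash(list(P, F))
      )
    ),
    class = "motif_tree"
  )
  tree$sigma_max <- sigma_max(tree)
  tree$sigma_opt <- sigma_opt(tree)
  tree
}

# AICc of a clustering tree level; NA when n - m + 1 <= 0 (or n - m - 1 <= 0
# for the textbook variant) or when the RSS is numerically zero (the
# log-likelihood term diverges). `rss_floor` guards against accumulated
# floating-point crumbs being mistaken for a real residual: an RSS at or
# below it is a perfect fit.
aicc_value <- function(n, m, rss, denominator = "n-m+1", rss_floor = 0) {
  denom <- if (denominator == "n-m+1") n - m + 1 else n - m - 1
  out <- n * log(rss / n) + 2 * m + 2 * m * (m + 1) / denom
  out[denom <= 0 | rss <= rss_floor] <- NA_real_
  out
}

# numerically-zero threshold for tree residual sums of squares
perfect_fit_floor <- function(tss) tss * 1e-12

#' Worst-case number of candidate clusterings scored by a full tree build
#'
#' Splitting a group of `q` species scores at most `q(q+1)/2 - 1` candidate
#' partitions; summed over all levels of the divisive tree this is bounded
#' by `s[(s+1)(s+2)/6 - 1]`, a tiny fraction of the Bell number of possible
#' species clusterings (see [count_partitions()]).
#'
#' @param s Number of species (>= 2).
#' @return The integer bound `s(s+1)(s+2)/6 - s`.
#' @export
#' @examples
#' max_evaluations(6) # 50
#' max_evaluations(16) # 800
max_evaluations <- function(s) {
  if (any(s < 2)) abort("`s` must be at least 2.")
  s * (s + 1) * (s + 2) / 6 - s
}

#' Number of possible partitions of s species (Bell number)
#'
#' Counts all ways to cluster `s` labelled species into any number of
#' non-empty functional groups, via the Bell-triangle recurrence. This is
#' the size of the search space that the divisive tree shortcuts.
#'
#' @param s Number of species (>= 1).
#' @return The Bell number B(s) as a double (exact up to B(25)).
#' @export
#' @examples
#' count_partitions(6) # 203
count_partitions <- function(s) {
  if (s < 1) abort("`s` must be at least 1.")
  row <- 1
  for (i in seq_len(s - 1)) {
    nxt <- numeric(length(row) + 1)
    nxt[1] <- row[length(row)]
    for (j in seq_along(row)) nxt[j + 1] <- nxt[j] + row[j]
    row <- nxt
  }
  row[length(row)]
}

#' @export
print.motif_tree <- function(x, ...) {
  cat(sprintf(
    "<motif_tree> %d species, %d ecosystems, %d levels\n",
    x$s, x$n, x$s
  ))
  cat(sprintf(
    "  evaluations: %d (bound %d)\n",
    x$evaluation_count, if (x$s >= 2) max_evaluations(x$s) else 0L
  ))
  cat(sprintf(
    "  sigma_max = %d (validated depth), sigma_opt = %d (AICc optimum)\n",
    x$sigma_max, x$sigma_opt
  ))
  opt <- x$sigma_opt
  cat(sprintf(
    "  at sigma_opt: R2_tree = %.4f, E_tree = %.4f\n",
    x$tree_stats$r2_tree[opt], x$tree_stats$e_tree[opt]
  ))
  grp <- partition_groups(x$partitions[[opt]])
  for (j in seq_along(grp)) {
    cat(sprintf("    group %d: %s\n", j, paste(x$species[grp[[j]]], collapse = ", ")))
  }
  invisible(x)
}

#' Per-level statistics of a clustering tree
#'
#' @param x A [build_tree()] result.
#' @param ... Unused.
#' @return A tibble with one row per level `sigma`: number of observed
#'   motifs `m`, model-level `rss_modelling`, `r_squared`, `rss_predicting`,
#'   `efficiency`, `predicting_ratio`, and whole-tree `r2_tree`, `e_tree`,
#'   `predicting_ratio_tree`, `aicc`.
#' @export
tidy.motif_tree <- function(x, ...) {
  dplyr::left_join(x$level_stats, x$tree_stats, by = "sigma")
}

#' One-row summary of a clustering tree
#'
#' @param x A [build_tree()] result.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, evaluation count, validated depth
#'   `sigma_max`, AICc optimum `sigma_opt`, and tree statistics at the
#'   optimum.
#' @export
glance.motif_tree <- function(x, ...) {
  opt <- x$sigma_opt
  tibble::tibble(
    n = x$n,
    s = x$s,
    evaluation_count = x$evaluation_count,
    sigma_max = x$sigma_max,
    sigma_opt = opt,
    m_opt = x$level_stats$m[opt],
    r2_tree = x$tree_stats$r2_tree[opt],
    e_tree = x$tree_stats$e_tree[opt],
    aicc_opt = x$tree_stats$aicc[opt]
  )
}

#' Diagnostic plot of a clustering tree
#'
#' Displays, against the number of functional groups: the model-level and
#' tree-level coefficients of determination and efficiencies, the predicting
#' ratio, and the tree AICc with its minimum (the selected number of
#' groups).
#'
#' @param object A [build_tree()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_tree <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::select(
      sigma, r_squared, efficiency, predicting_ratio,
      r2_tree, e_tree, aicc
    ) |>
    tidyr::pivot_longer(-sigma, names_to = "statistic", values_to = "value") |>
    dplyr::mutate(panel = ifelse(.data$statistic == "aicc", "AICc", "fit statistics"))
  ggplot2::ggplot(df, ggplot2::aes(.data$sigma, .data$value, colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$sigma_opt, linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(
      x = "number of functional groups",
      y = NULL,
      title = "Divisive clustering tree diagnostics",
      subtitle = sprintf(
        "sigma_max = %d, sigma_opt = %d",
        object$sigma_max, object$sigma_opt
      )
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
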