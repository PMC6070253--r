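#' Fit a single-level motif model
#'
#' Evaluates one species partition (a "sigma-model") against an ecosystem
#' sample: modelled function values, the coefficient of determination
#' `R^2 = 1 - RSS_modelling / TSS`, leave-one-out predictions, and the
#' cross-validated efficiency `E = 1 - RSS_predicting / TSS` (a
#' Nash-Sutcliffe-type coefficient that may be negative).
#'
#' Because ecosystems that are sole representatives of their motif have no
#' defined prediction, `RSS_predicting` can only sum over the predictable
#' subset. By default (`tss = "subset"`) the efficiency is normalized by the
#' total sum of squares of that same subset, so that models leaving
#' different subsets predictable remain on a comparable scale;
#' `tss = "full"` normalizes by the full-sample TSS instead.
#'
#' @inheritParams assign_motifs
#' @param tss Normalization of the efficiency denominator: `"subset"`
#'   (default) or `"full"`.
#' @return An object of class `motif_fit`; see [tidy.motif_fit()] and
#'   [glance.motif_fit()] for tibble views. Fields include `sigma`, `m`,
#'   `tss`, `rss_modelling`, `r_squared`, `rss_predicting`, `efficiency`,
#'   `predicting_ratio`, `modelled`, `predicted`, `defined`.
#' @export
#' @examples
#' toy <- eco_sample(tibble::tibble(
#'   id = paste0("e", 1:5),
#'   X = c(1, 1, 1, 0, 1), Y = c(0, 1, 0, 1, 1), Z = c(0, 0, 1, 1, 1),
#'   f = c(10, 20, 24, 8, 22)
#' ))
#' fit <- motif_fit(toy, c(X = 1, Y = 2, Z = 2))
#' glance(fit)
motif_fit <- function(sample, partition, tss = c("subset", "full")) {
  stopifnot(inherits(sample, "eco_sample"))
  tss <- match.arg(tss)
  if (n_ecosystems(sample) < 2) abort("Fitting needs at least 2 ecosystems.")
  cls <- assign_motifs(sample, partition)
  F <- sample$function_values
  tss_all <- total_ss(F)
  if (tss_all == 0) {
    abort("Degenerate variance: all observed function values are equal (TSS = 0).")
  }
  modelled <- modelled_function(sample, cls)
  rss_mod <- sum((F - modelled)^2)
  loo <- loo_predictions(sample, cls)
  eff <- efficiency_of(F, loo$predicted, tss_all, tss)

  structure(
    list(
      sigma = n_groups(cls$partition),
      partition = cls$partition,
      m = cls$m,
      motif_key = cls$motif_key,
      tss = tss_all,
      tss_variant = tss,
      rss_modelling = rss_mod,
      r_squared = 1 - rss_mod / tss_all,
      rss_predicting = eff$rss_predicting,
      efficiency = eff$efficiency,
      predicting_ratio = loo$predicting_ratio,
      modelled = modelled,
      predicted = loo$predicted,
      defined = loo$defined,
      observed = F,
      ecosystem_ids = sample$ecosystem_ids
    ),
    class = "motif_fit"
  )
}

# efficiency of LOO predictions; NA (undefined) with fewer than 2 predictable
# ecosystems. With a constant predictable subset (subset TSS = 0) E is 1 for
# perfect predictions and undefined otherwise.
efficiency_of <- function(F, predicted, tss_all, tss_variant = "subset") {
  d <- !is.na(predicted)
  if (sum(d) < 2) {
    return(list(rss_predicting = NA_real_, efficiency = NA_real_))
  }
  rss_pred <- sum((F[d] - predicted[d])^2)
  denom <- if (tss_variant == "full") tss_all else total_ss(F[d])
  eff <- if (denom > 0) {
    1 - rss_pred / denom
  } else if (rss_pred == 0) {
    1
  } else {
    NA_real_
  }
  list(rss_predicting = rss_pred, efficiency = eff)
}

#' @export
print.motif_fit <- function(x, ...) {
  cat(sprintf(
    "<motif_fit> sigma = %d, m = %d motifs, n = %d ecosystems\n",
    x$sigma, x$m, length(x$observed)
  ))
  cat(sprintf(
    "  R^2 = %.4f, E = %s, predicting ratio = %.3f\n",
    x$r_squared,
    if (is.na(x$efficiency)) "undefined" else sprintf("%.4f", x$efficiency),
    x$predicting_ratio
  ))
  invisible(x)
}

#' Tidy a motif-model fit into per-ecosystem rows
#'
#' @param x A [motif_fit()].
#' @param ... Unused.
#' @return A tibble with one row per ecosystem: id, motif, observed,
#'   modelled, predicted function and whether the prediction is defined.
#' @export
tidy.motif_fit <- function(x, ...) {
  tibble::tibble(
    ecosystem_id = x$ecosystem_ids,
    motif = x$motif_key,
    observed = x$observed,
    modelled = x$modelled,
    predicted = x$predicted,
    defined = x$defined
  )
}

#' One-row summary of a motif-model fit
#'
#' @param x A [motif_fit()].
#' @param ... Unused.
#' @return A one-row tibble: `sigma`, `m`, `tss`, `rss_modelling`,
#'   `r_squared`, `rss_predicting`, `efficiency`, `predicting_ratio`.
#' @export
glance.motif_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma,
    m = x$m,
    tss = x$tss,
    rss_modelling = x$rss_modelling,
    r_squared = x$r_squared,
    rss_predicting = x$rss_predicting,
    efficiency = x$efficiency,
    predicting_ratio = x$predicting_ratio
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
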